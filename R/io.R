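#' Read a reflectivity data file
#'
#' Parses 2-4 column whitespace- or comma-delimited text (Q, R, optional
#' dR and dQ, Q in A^-1).  Lines starting with `#` are ignored, which
#' also covers ORSO-style `.ort` headers.  Rows are sorted by Q;
#' duplicate or non-positive Q and non-numeric rows are rejected with the
#' offending line number.
#'
#' @param path Path to the file.
#' @param contrast Optional [contrast_spec] to attach.
#' @return A [reflectivity_curve].
#' @export
read_reflectivity <- function(path, contrast = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data rows in ", path)
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (any(is.na(val))) {
      stop(sprintf("non-numeric value on line %d of %s", i, path))
    }
    if (length(val) < 2 || length(val) > 4) {
      stop(sprintf("expected 2-4 columns on line %d of %s, got %d",
                   i, path, length(val)))
    }
    val
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop(sprintf("inconsistent column count at line %d of %s",
                 keep[which(ncols != ncols[1])[1]], path))
  }
  m <- do.call(rbind, rows)
  q <- m[, 1]
  bad <- which(q <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive Q on line %d of %s", keep[bad[1]], path))
  }
  if (max(q) > 2) {
    stop("Q_max > 2: Q must be in 1/Angstrom (nm^-1 data are not ",
         "auto-converted)")
  }
  dup <- which(duplicated(q))
  if (length(dup)) {
    stop(sprintf("duplicate Q value on line %d of %s", keep[dup[1]], path))
  }
  o <- order(q)
  reflectivity_curve(q[o], m[o, 2],
                     dr = if (ncol(m) >= 3) m[o, 3],
                     dq = if (ncol(m) >= 4) m[o, 4],
                     contrast = contrast)
}

#' Write a reflectivity curve
#'
#' Multi-column text (Q, R, dR, dQ as available), 8 significant digits,
#' with a short `#` header; round-trips through [read_reflectivity()].
#'
#' @param curve A [reflectivity_curve].
#' @param path Output path.
#' @export
write_reflectivity <- function(curve, path) {
  stopifnot(inherits(curve, "reflectivity_curve"))
  cols <- intersect(c("q", "r", "dr", "dq"), names(curve))
  ct <- attr(curve, "contrast")
  header <- c(
    "# reflectivity data written by slabnr",
    if (!is.null(ct)) sprintf("# d2o_fraction: %g", ct$d2o_fraction),
    paste("#", paste(toupper(cols), collapse = " "))
  )
  body <- apply(as.matrix(curve[cols]), 1, function(x)
    paste(sprintf("%.8g", x), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' The run configuration is a single YAML file describing the model
#' (type, SLD anchors, parameter overrides, vesicle switch), the contrast
#' list (D2O fractions), the instrument, seeds, and -- for fitting -- the
#' data files.  It is schema-checked before any computation.
#'
#' @param path Path to the YAML file.
#' @return Validated list of class `"run_config"` with the constructed
#'   `model` ([slb_model]) and `instrument` ([instrument_spec]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("model", "contrasts")) {
    if (is.null(cfg[[field]])) stop("config lacks required field: ", field)
  }
  if (is.null(cfg$model$type)) stop("config model lacks 'type'")
  params <- cfg$model$params
  model <- slb_model(
    type = cfg$model$type,
    params = params,
    sld = cfg$model$sld,
    substrate = cfg$model$substrate,
    volumes = cfg$model$volumes,
    vesicles_in = cfg$model$vesicles_in %||% "none",
    background = cfg$model$background %||% 1e-7
  )
  contrasts <- as.numeric(cfg$contrasts)
  if (any(contrasts < 0) || any(contrasts > 1)) {
    stop("contrasts must be D2O volume fractions in [0, 1]")
  }
  instrument <- do.call(instrument_spec,
                        as.list(cfg$instrument %||% list()))
  if (!is.null(cfg$data)) {
    if (length(cfg$data) != length(contrasts)) {
      stop("'data' must list one file per contrast")
    }
    missing <- cfg$data[!file.exists(file.path(dirname(path), cfg$data)) &
                        !file.exists(cfg$data)]
    if (length(missing)) {
      stop("data file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(model = model, contrasts = contrasts, instrument = instrument,
         seed = cfg$seed %||% 1L,
         fit = utils::modifyList(list(n_starts = 8, jitter = 0.2),
                                 as.list(cfg$fit %||% list())),
         data = cfg$data, dir = dirname(path),
         output = cfg$output %||% "."),
    class = "run_config"
  )
}

.resolve_paths <- function(config, files) {
  ifelse(file.exists(files), files, file.path(config$dir, files))
}

.contrast_name <- function(f) {
  if (f == 0) "H2O" else if (f == 1) "D2O" else sprintf("D2O_%02.0f", 100 * f)
}

#' Simulate datasets from a run configuration
#'
#' Generates one reflectivity file per configured contrast from the
#' configured model (treated as ground truth) plus a YAML truth sidecar
#' for later recovery scoring.
#'
#' @param config A `"run_config"` or a path to one.
#' @param out_dir Output directory (default: the config's `output`).
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- simulate_contrast_series(config$model, config$contrasts,
                                   config$instrument, seed = config$seed)
  paths <- character(0)
  for (nm in names(data)) {
    p <- file.path(out_dir, paste0(nm, ".dat"))
    write_reflectivity(data[[nm]], p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(
    list(model_type = config$model$type,
         parameters = as.list(attr(data, "truth")),
         derived = as.list(derived_quantities(config$model)),
         sld = config$model$sld,
         seed = config$seed),
    truth_path)
  message("wrote ", length(paths), " dataset(s) and truth sidecar to ",
          out_dir)
  invisible(c(paths, truth_path))
}

#' Fit configured data files by co-refinement
#'
#' Reads the configured data files (one per contrast), co-refines the
#' configured model, and writes a human-readable report, a
#' self-contained YAML fit artifact and per-contrast model curves in the
#' input column format.
#'
#' @inheritParams run_simulate
#' @return The `slb_fit`, invisibly.
#' @export
run_fit <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$data)) stop("config has no 'data' files to fit")
  out_dir <- out_dir %||% config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- .resolve_paths(config, config$data)
  data <- stats::setNames(
    lapply(seq_along(paths), function(i) {
      read_reflectivity(paths[i],
                        contrast = contrast_spec(
                          config$contrasts[i],
                          config$instrument$dq_over_q))
    }),
    vapply(config$contrasts, .contrast_name, character(1)))
  fit <- nr_corefine(config$model, data,
                     n_starts = config$fit$n_starts,
                     seed = config$seed, jitter = config$fit$jitter)
  write_fit_artifact(fit, file.path(out_dir, "fit.yaml"))
  report_lines <- utils::capture.output(print(summary(fit)))
  writeLines(report_lines, file.path(out_dir, "report.txt"))
  for (nm in names(fit$curves)) {
    curve <- fit$curves[[nm]]
    writeLines(
      c("# model curve (Q, R)",
        sprintf("%.8g %.8g", curve$q, curve$r_model)),
      file.path(out_dir, paste0("model_", nm, ".dat")))
  }
  message("fit written to ", out_dir,
          sprintf(" (chi2 = %.4g, reduced %.4g)",
                  fit$chisq_total, fit$chisq_reduced))
  invisible(fit)
}

#' Write / read a self-contained fit artifact
#'
#' The artifact is YAML carrying the model definition, the full parameter
#' table with fitted values, derived quantities and the chi-square
#' breakdown -- everything needed to re-print the report without the
#' original data.
#'
#' @param fit An `slb_fit`.
#' @param path Artifact path.
#' @return `write_fit_artifact`: the path, invisibly;
#'   `read_fit_artifact`: the artifact as a list.
#' @export
write_fit_artifact <- function(fit, path) {
  stopifnot(inherits(fit, "slb_fit"))
  yaml::write_yaml(
    list(
      model = list(type = fit$model$type, sld = fit$model$sld,
                   substrate = fit$model$substrate,
                   volumes = fit$model$volumes,
                   vesicles_in = fit$model$vesicles_in,
                   background = fit$model$background),
      parameters = lapply(seq_len(nrow(fit$par_table)), function(i)
        as.list(fit$par_table[i, ])),
      derived = as.list(fit$derived),
      chisq = list(per_contrast = as.list(fit$chisq),
                   total = fit$chisq_total,
                   reduced = fit$chisq_reduced,
                   n_points = fit$n_points, n_free = fit$n_free),
      n_starts = fit$n_starts, seed = fit$seed),
    path)
  invisible(path)
}

#' @rdname write_fit_artifact
#' @export
read_fit_artifact <- function(path) {
  if (!file.exists(path)) stop("artifact not found: ", path)
  yaml::read_yaml(path)
}

#' Print the layer table of a stored fit artifact
#'
#' Rebuilds the model from the artifact alone and prints the same layer
#' table and chi-square summary as [run_fit()] reported.
#'
#' @param artifact Path to a YAML artifact from [write_fit_artifact()],
#'   or the list returned by [read_fit_artifact()].
#' @return The layer table, invisibly.
#' @export
run_report <- function(artifact) {
  if (is.character(artifact)) artifact <- read_fit_artifact(artifact)
  partab <- do.call(rbind, lapply(artifact$parameters, as.data.frame))
  model <- slb_model(
    type = artifact$model$type,
    params = stats::setNames(
      lapply(seq_len(nrow(partab)), function(i)
        list(init = partab$fitted[i], min = partab$min[i],
             max = partab$max[i], vary = partab$vary[i])),
      partab$name),
    sld = artifact$model$sld,
    substrate = artifact$model$substrate,
    volumes = artifact$model$volumes,
    vesicles_in = artifact$model$vesicles_in,
    background = artifact$model$background
  )
  tab <- layer_table(model)
  cat(sprintf("Model: %s; chi2 = %.4g (reduced %.4g)\n",
              artifact$model$type, artifact$chisq$total,
              artifact$chisq$reduced))
  print(tab, row.names = FALSE)
  invisible(tab)
}
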