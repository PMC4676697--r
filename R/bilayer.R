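#' Area per molecule from the tail region
#'
#' The hydrocarbon region of a bilayer holds the chains of both leaflets,
#' so the mean interfacial area per lipid is
#' `A = 2 V_tails / (d_t (1 - phi_t))`.
#'
#' @param d_t Tail-region thickness, A (> 0).
#' @param phi_t Tail-region solvent fraction, `[0, 1)`.
#' @param v_tails Tail volume per lipid, A^3 (default: POPC, 937).
#' @return Area per molecule in A^2.
#' @export
area_per_molecule <- function(d_t, phi_t, v_tails = 937) {
  if (any(d_t <= 0)) stop("'d_t' must be > 0")
  if (any(phi_t < 0) || any(phi_t >= 1)) {
    stop("'phi_t' must lie in [0, 1): phi_t = 1 leaves no lipid")
  }
  2 * v_tails / (d_t * (1 - phi_t))
}

#' Headgroup solvent fraction coupled to the tail area
#'
#' Requiring identical mean molecular areas for the headgroup and tail
#' regions fixes the headgroup hydration: `phi_h = 1 - V_head / (d_h A)`.
#' Values outside `[0, 1]` signal inconsistent volume choices; they are
#' clamped with a warning rather than failing.
#'
#' @param d_h Headgroup-layer thickness, A (> 0).
#' @param area Area per molecule, A^2 (> 0), from [area_per_molecule()].
#' @param v_head Headgroup volume per lipid, A^3 (default: POPC, 319).
#' @return Headgroup solvent fraction in `[0, 1]`.
#' @export
coupled_head_solvent <- function(d_h, area, v_head = 319) {
  if (any(d_h <= 0)) stop("'d_h' must be > 0")
  if (any(area <= 0)) stop("'area' must be > 0")
  phi <- 1 - v_head / (d_h * area)
  if (any(phi < 0) || any(phi > 1)) {
    warning("coupled headgroup solvent fraction outside [0, 1]; ",
            "clamped (check head/tail volumes)")
    phi <- pmin(pmax(phi, 0), 1)
  }
  phi
}

.default_params <- function(type) {
  if (type == "three_layer") {
    data.frame(
      name = c("d_water", "d_head", "d_tail", "phi_tail", "sigma",
               "dsld_head", "dsld_tail"),
      init = c(8, 7, 27, 0.12, 4, 0, 0),
      min  = c(0, 3, 15, 0, 0.5, -0.5, -0.5),
      max  = c(25, 15, 40, 0.6, 15, 0.5, 0.5),
      vary = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = c("d_water", "d_bilayer", "phi_bilayer", "sigma",
               "d_vwater", "coverage", "sigma_ves", "dsld_bilayer"),
      init = c(9, 41, 0.06, 7, 14, 0.04, 10, 0),
      min  = c(0, 25, 0, 0.5, 5, 0, 0.5, -0.5),
      max  = c(25, 60, 0.5, 15, 30, 0.3, 20, 0.5),
      vary = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
  }
}

#' Define a constrained bilayer parameterization
#'
#' Two structural models for a supported lipid bilayer (SLB) on
#' Si/SiO2, each producing one slab stack per water contrast while all
#' structural parameters are shared across contrasts:
#'
#' * `"three_layer"` — interfacial water gap, then a symmetric
#'   head-tail-head bilayer.  The headgroup solvent fraction is never
#'   fitted: it is derived from the equal-area constraint
#'   ([coupled_head_solvent()]).  Headgroup SLD follows the solvent via
#'   labile-proton exchange between its H2O and D2O endpoints.
#' * `"one_layer_vesicles"` — water gap plus a single bilayer slab, with
#'   an optional sparse vesicle extension: a further water gap and a
#'   dilute bilayer slab whose thickness and SLD are tied to the SLB and
#'   whose lipid volume fraction is the vesicle coverage.
#'
#' Free parameters (thicknesses in A, fractions dimensionless, SLD
#' offsets in 1e-6 A^-2) carry `init`/`min`/`max`/`vary` entries; use
#' `params` to override any of them.
#'
#' @param type `"three_layer"` or `"one_layer_vesicles"`.
#' @param params Named list of overrides, e.g.
#'   `list(d_head = list(init = 8, vary = FALSE))`.
#' @param sld Fixed SLD anchors in 1e-6 A^-2.  For `three_layer`:
#'   `head_h2o`, `head_d2o`, `tail` (defaults 1.55, 2.16, -0.55).  For
#'   `one_layer_vesicles`: `bilayer` (default 6.66).  Compute them from
#'   composition with [mixture_region_slds()] or take fitted literature
#'   values; the fittable `dsld_*` offsets (bounded +/- 0.5) absorb small
#'   discrepancies.
#' @param substrate Characterised substrate: `sio2_d`, `sio2_sld`,
#'   `sio2_phi`, `sio2_roughness` (defaults 12 A, 3.47, 0, 3 A).
#' @param volumes Reference molecular volumes for the equal-area
#'   constraint: `head`, `tails` (POPC defaults 319 and 937 A^3).
#' @param vesicles_in When the vesicle extension applies:
#'   `"none"`, `"h2o_only"` (contrasts with D2O fraction <= 0.05) or
#'   `"all"`.
#' @param background Constant instrumental background added to every
#'   model curve (default 1e-7).
#' @return An object of class `"slb_model"`.
#' @examples
#' m <- slb_model("three_layer")
#' build_slab_stack(m, contrast = contrast_spec(1))
#' @export
slb_model <- function(type = c("three_layer", "one_layer_vesicles"),
                      params = NULL,
                      sld = NULL,
                      substrate = NULL,
                      volumes = NULL,
                      vesicles_in = c("none", "h2o_only", "all"),
                      background = 1e-7) {
  type <- match.arg(type)
  vesicles_in <- match.arg(vesicles_in)
  if (type == "three_layer" && vesicles_in != "none") {
    stop("the vesicle extension applies to the one-layer model only")
  }
  tab <- .default_params(type)
  if (!is.null(params)) {
    for (nm in names(params)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("unknown parameter: ", nm)
      ov <- params[[nm]]
      if (is.numeric(ov)) ov <- list(init = ov)
      for (fld in intersect(names(ov), c("init", "min", "max", "vary"))) {
        tab[[fld]][i] <- ov[[fld]]
      }
    }
  }
  bad <- tab$vary & (!is.finite(tab$min) | !is.finite(tab$max))
  if (any(bad)) {
    stop("varied parameter(s) without finite bounds: ",
         paste(tab$name[bad], collapse = ", "))
  }
  if (any(tab$init < tab$min | tab$init > tab$max)) {
    stop("initial value outside bounds")
  }
  sld_def <- if (type == "three_layer") {
    list(head_h2o = 1.55, head_d2o = 2.16, tail = -0.55)
  } else {
    list(bilayer = 6.66)
  }
  sld <- utils::modifyList(sld_def, as.list(sld %||% list()))
  substrate <- utils::modifyList(
    list(sio2_d = 12, sio2_sld = 3.47, sio2_phi = 0, sio2_roughness = 3),
    as.list(substrate %||% list()))
  volumes <- utils::modifyList(list(head = 319, tails = 937),
                               as.list(volumes %||% list()))
  structure(
    list(type = type, params = tab, sld = sld, substrate = substrate,
         volumes = volumes, vesicles_in = vesicles_in,
         background = background),
    class = "slb_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.slb_model <- function(x, ...) {
  cat(sprintf("<slb_model> %s (vesicles: %s)\n", x$type, x$vesicles_in))
  print(x$params, row.names = FALSE)
  cat("SLD anchors (1e-6/A^2):",
      paste(names(x$sld), unlist(x$sld), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# named vector of all parameter values (init unless overridden)
.par_vector <- function(model, values = NULL) {
  p <- stats::setNames(model$params$init, model$params$name)
  if (!is.null(values)) p[names(values)] <- values
  p
}

.has_vesicles <- function(model, contrast) {
  switch(model$vesicles_in,
         none = FALSE,
         all = TRUE,
         h2o_only = contrast$d2o_fraction <= 0.05)
}

#' Build the per-contrast slab stack of a bilayer model
#'
#' Realises a parameter vector of an [slb_model] as a [slab_stack] for a
#' given solvent contrast.  Structural fields are contrast-independent;
#' only solvent-dependent SLDs (headgroup exchange, solvent penetration)
#' differ between contrasts.  An equal-area constraint violation
#' (headgroup solvent fraction outside `[0, 1]`) is clamped and recorded
#' in the `"constraint_violation"` attribute rather than raising an
#' error, so an optimiser can penalise it.
#'
#' @param model An [slb_model].
#' @param par Named parameter vector; defaults to the model's `init`
#'   values.  Partial vectors override the defaults.
#' @param contrast A [contrast_spec].
#' @return A [slab_stack] with attribute `"constraint_violation"`
#'   (0 when the constraint is satisfied).
#' @export
build_slab_stack <- function(model, par = NULL, contrast) {
  stopifnot(inherits(model, "slb_model"), inherits(contrast, "contrast_spec"))
  p <- .par_vector(model, par)
  sub <- model$substrate
  sio2 <- slab(sub$sio2_d, sub$sio2_sld, sub$sio2_phi, sub$sio2_roughness,
               name = "SiO2")
  f <- contrast$d2o_fraction
  violation <- 0
  if (model$type == "three_layer") {
    area <- area_per_molecule(p[["d_tail"]], p[["phi_tail"]],
                              model$volumes$tails)
    phi_h_raw <- 1 - model$volumes$head / (p[["d_head"]] * area)
    violation <- max(0, -phi_h_raw, phi_h_raw - 1)
    phi_h <- min(max(phi_h_raw, 0), 1)
    sld_head <- exchanged_sld(model$sld$head_h2o, model$sld$head_d2o, f) +
      p[["dsld_head"]]
    sld_tail <- model$sld$tail + p[["dsld_tail"]]
    s <- p[["sigma"]]
    slabs <- list(
      sio2,
      slab(p[["d_water"]], 0, 1, s, name = "water*"),
      slab(p[["d_head"]], sld_head, phi_h, s, name = "head"),
      slab(p[["d_tail"]], sld_tail, p[["phi_tail"]], s, name = "tail"),
      slab(p[["d_head"]], sld_head, phi_h, s, name = "head")
    )
    backing_sigma <- s
  } else {
    sld_bl <- model$sld$bilayer + p[["dsld_bilayer"]]
    s <- p[["sigma"]]
    slabs <- list(
      sio2,
      slab(p[["d_water"]], 0, 1, s, name = "water*"),
      slab(p[["d_bilayer"]], sld_bl, p[["phi_bilayer"]], s, name = "bilayer")
    )
    backing_sigma <- s
    if (.has_vesicles(model, contrast)) {
      # the gap's lower interface is the SLB's top surface (roughness s);
      # only the diffuse vesicle material carries sigma_ves
      sv <- p[["sigma_ves"]]
      slabs <- c(slabs, list(
        slab(p[["d_vwater"]], 0, 1, s, name = "water(ves)"),
        slab(p[["d_bilayer"]], sld_bl, 1 - p[["coverage"]], sv,
             name = "bilayer(ves)")
      ))
      backing_sigma <- sv
    }
  }
  st <- suppressWarnings(
    slab_stack(slabs, fronting_sld = 2.07, backing_roughness = backing_sigma))
  attr(st, "constraint_violation") <- violation
  st
}

# Fast path for fitting: effective-layer vectors (d, solvent-mixed rho,
# sigma) without slab/data.frame construction.  Must stay equivalent to
# build_slab_stack(); the test suite checks the two against each other.
.layer_vectors <- function(model, p, contrast) {
  sub <- model$substrate
  f <- contrast$d2o_fraction
  solvent <- contrast$water_sld
  violation <- 0
  if (model$type == "three_layer") {
    area <- 2 * model$volumes$tails / (p[["d_tail"]] * (1 - p[["phi_tail"]]))
    phi_h_raw <- 1 - model$volumes$head / (p[["d_head"]] * area)
    violation <- max(0, -phi_h_raw, phi_h_raw - 1)
    phi_h <- min(max(phi_h_raw, 0), 1)
    sld_head <- (1 - f) * model$sld$head_h2o + f * model$sld$head_d2o +
      p[["dsld_head"]]
    sld_tail <- model$sld$tail + p[["dsld_tail"]]
    s <- p[["sigma"]]
    d <- c(0, sub$sio2_d, p[["d_water"]], p[["d_head"]], p[["d_tail"]],
           p[["d_head"]], 0)
    intr <- c(2.07, sub$sio2_sld, 0, sld_head, sld_tail, sld_head, solvent)
    phi <- c(0, sub$sio2_phi, 1, phi_h, p[["phi_tail"]], phi_h, 1)
    sigma <- c(0, sub$sio2_roughness, s, s, s, s, s)
  } else {
    sld_bl <- model$sld$bilayer + p[["dsld_bilayer"]]
    s <- p[["sigma"]]
    if (.has_vesicles(model, contrast)) {
      sv <- p[["sigma_ves"]]
      d <- c(0, sub$sio2_d, p[["d_water"]], p[["d_bilayer"]],
             p[["d_vwater"]], p[["d_bilayer"]], 0)
      intr <- c(2.07, sub$sio2_sld, 0, sld_bl, 0, sld_bl, solvent)
      phi <- c(0, sub$sio2_phi, 1, p[["phi_bilayer"]], 1,
               1 - p[["coverage"]], 1)
      sigma <- c(0, sub$sio2_roughness, s, s, s, sv, sv)
    } else {
      d <- c(0, sub$sio2_d, p[["d_water"]], p[["d_bilayer"]], 0)
      intr <- c(2.07, sub$sio2_sld, 0, sld_bl, solvent)
      phi <- c(0, sub$sio2_phi, 1, p[["phi_bilayer"]], 1)
      sigma <- c(0, sub$sio2_roughness, s, s, s)
    }
  }
  list(d = d, rho = phi * solvent + (1 - phi) * intr, sigma = sigma,
       violation = violation)
}

#' Derived structural quantities of a parameter vector
#'
#' @param model An [slb_model].
#' @param par Named parameter vector (defaults to `init` values).
#' @return Named numeric vector: for the three-layer model the area per
#'   molecule (`area`, A^2), coupled headgroup solvent fraction
#'   (`phi_head`) and total film thickness (`d_total = 2 d_head +
#'   d_tail`, A); for the one-layer model the bilayer thickness
#'   (`d_total`) and vesicle coverage in percent.
#' @export
derived_quantities <- function(model, par = NULL) {
  p <- .par_vector(model, par)
  if (model$type == "three_layer") {
    area <- area_per_molecule(p[["d_tail"]], p[["phi_tail"]],
                              model$volumes$tails)
    phi_h <- 1 - model$volumes$head / (p[["d_head"]] * area)
    c(area = area, phi_head = phi_h,
      d_total = 2 * p[["d_head"]] + p[["d_tail"]])
  } else {
    c(d_total = p[["d_bilayer"]], coverage_pct = 100 * p[["coverage"]])
  }
}

#' Table-style summary of a fitted or assumed structure
#'
#' One row per layer with thickness, solvent percentage, SLD and
#' interfacial roughness, plus a TOTAL row for the film thickness --
#' the conventional reporting format for slab-model fits.
#'
#' @param model An [slb_model].
#' @param par Named parameter vector (defaults to `init` values).
#' @return A data frame with columns `layer`, `d_A`, `solvent_pct`,
#'   `sld`, `roughness_A`.
#' @export
layer_table <- function(model, par = NULL) {
  p <- .par_vector(model, par)
  fmt <- function(x) round(x, 2)
  if (model$type == "three_layer") {
    dq <- derived_quantities(model, par)
    head_sld <- sprintf("%.2f/%.2f",
                        model$sld$head_h2o + p[["dsld_head"]],
                        model$sld$head_d2o + p[["dsld_head"]])
    out <- data.frame(
      layer = c("Water*", "Head", "Tail", "Head", "TOTAL"),
      d_A = fmt(c(p[["d_water"]], p[["d_head"]], p[["d_tail"]],
                  p[["d_head"]], dq[["d_total"]])),
      solvent_pct = c(100, rep(fmt(100 * dq[["phi_head"]]), 1),
                      fmt(100 * p[["phi_tail"]]),
                      fmt(100 * dq[["phi_head"]]), NA),
      sld = c(NA, head_sld, sprintf("%.2f", model$sld$tail + p[["dsld_tail"]]),
              head_sld, NA),
      roughness_A = c(rep(fmt(p[["sigma"]]), 4), NA),
      stringsAsFactors = FALSE
    )
  } else {
    ves <- model$vesicles_in != "none"
    sld_bl <- sprintf("%.2f", model$sld$bilayer + p[["dsld_bilayer"]])
    out <- data.frame(
      layer = c("Water*", "Bilayer",
                if (ves) c("Water(ves)", "Bilayer(ves)"), "TOTAL"),
      d_A = fmt(c(p[["d_water"]], p[["d_bilayer"]],
                  if (ves) c(p[["d_vwater"]], p[["d_bilayer"]]),
                  p[["d_bilayer"]])),
      solvent_pct = c(100, fmt(100 * p[["phi_bilayer"]]),
                      if (ves) c(100, fmt(100 * (1 - p[["coverage"]]))), NA),
      sld = c(NA, sld_bl, if (ves) c(NA, sld_bl), NA),
      roughness_A = c(fmt(p[["sigma"]]), fmt(p[["sigma"]]),
                      if (ves) rep(fmt(p[["sigma_ves"]]), 2), NA),
      stringsAsFactors = FALSE
    )
  }
  out
}
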