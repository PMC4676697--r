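#' Construct a slab (optical layer)
#'
#' One homogeneous layer of a stratified interfacial model: thickness,
#' intrinsic (dry) SLD, solvent volume fraction and the Gaussian roughness
#' of its interface to the preceding (substrate-side) layer.
#'
#' @param d Thickness in Angstrom, `>= 0`.
#' @param sld Intrinsic SLD in 1e-6 A^-2.
#' @param solvent_fraction Volume fraction of solvent in `[0, 1]`.
#' @param roughness Roughness sigma (A) of the substrate-side interface.
#' @param name Optional label.
#' @return An object of class `"slab"`.
#' @export
slab <- function(d, sld, solvent_fraction = 0, roughness = 0,
                 name = "layer") {
  stopifnot(length(d) == 1L, length(sld) == 1L,
            length(solvent_fraction) == 1L, length(roughness) == 1L)
  if (!is.finite(d) || d < 0) stop("'d' must be finite and >= 0")
  if (!is.finite(sld)) stop("'sld' must be finite")
  if (solvent_fraction < 0 || solvent_fraction > 1) {
    stop("'solvent_fraction' must lie in [0, 1]")
  }
  if (!is.finite(roughness) || roughness < 0) {
    stop("'roughness' must be finite and >= 0")
  }
  structure(list(d = d, sld = sld, solvent_fraction = solvent_fraction,
                 roughness = roughness, name = name),
            class = "slab")
}

#' Effective SLD of a solvent-penetrated slab
#'
#' The solvent volume fraction phi mixes the layer's intrinsic SLD with
#' the solvent's: `rho_eff = phi * rho_solvent + (1 - phi) * rho_slab`.
#'
#' @param slab A [slab] (or a list with `sld` and `solvent_fraction`).
#' @param solvent_sld Solvent SLD in 1e-6 A^-2.
#' @return Effective SLD in 1e-6 A^-2.
#' @export
effective_sld <- function(slab, solvent_sld) {
  phi <- slab$solvent_fraction
  phi * solvent_sld + (1 - phi) * slab$sld
}

#' Assemble a slab stack at the solid-liquid interface
#'
#' The stack is evaluated beam-side first: semi-infinite silicon fronting,
#' then the slabs in order (SiO2 first, film layers after), then the
#' semi-infinite solvent backing.  Fronting and backing have no thickness.
#'
#' @param slabs List of [slab]s, substrate side first.
#' @param fronting_sld SLD of the incident medium (silicon, 2.07).
#' @param backing_roughness Roughness sigma (A) of the final
#'   slab-to-solvent interface.
#' @return An object of class `"slab_stack"`: a data frame with one row
#'   per layer (including fronting and backing) and columns `name`, `d`,
#'   `sld`, `solvent_fraction`, `roughness`.  `roughness` on a row is the
#'   sigma of that layer's substrate-side interface; the backing row's
#'   `sld` is `NA` and is substituted by the solvent SLD at evaluation.
#' @export
slab_stack <- function(slabs = list(), fronting_sld = 2.07,
                       backing_roughness = 0) {
  if (inherits(slabs, "slab")) slabs <- list(slabs)
  stopifnot(all(vapply(slabs, inherits, logical(1), "slab")))
  rows <- data.frame(
    name = c("fronting",
             vapply(slabs, `[[`, character(1), "name"),
             "backing"),
    d = c(0, vapply(slabs, `[[`, numeric(1), "d"), 0),
    sld = c(fronting_sld, vapply(slabs, `[[`, numeric(1), "sld"), NA_real_),
    solvent_fraction = c(0,
                         vapply(slabs, `[[`, numeric(1), "solvent_fraction"),
                         1),
    roughness = c(0, vapply(slabs, `[[`, numeric(1), "roughness"),
                  backing_roughness),
    stringsAsFactors = FALSE
  )
  # sigma much larger than an adjoining layer invalidates the Nevot-Croce
  # approximation only gradually; warn rather than fail
  n <- nrow(rows)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      dmin <- min(rows$d[i], if (i > 2) rows$d[i - 1] else Inf)
      if (rows$roughness[i] > dmin && dmin > 0) {
        warning(sprintf(
          "roughness %.3g A of layer '%s' exceeds the thinner adjoining layer (%.3g A)",
          rows$roughness[i], rows$name[i], dmin))
      }
    }
  }
  structure(rows, class = c("slab_stack", "data.frame"))
}

#' @export
print.slab_stack <- function(x, ...) {
  cat("<slab_stack> Si -> solvent,", nrow(x) - 2, "slabs\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
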