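#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths, in fm, for the elements occurring in
#' phospholipids and their solvents.  `D` is deuterium (2H); all other
#' symbols are natural-abundance elements.
#'
#' @format Named numeric vector, units fm.
#' @export
coherent_b <- c(
  H = -3.739,
  D = 6.671,
  C = 6.646,
  N = 9.36,
  O = 5.803,
  P = 5.13
)

#' Construct a molecular fragment
#'
#' A fragment is the bookkeeping unit for scattering-length-density (SLD)
#' calculations: an elemental/isotopic formula, a molecular volume and the
#' number of labile (solvent-exchangeable) hydrogens.
#'
#' @param name Character label.
#' @param formula Named numeric vector of atom counts, e.g.
#'   `c(H = 12, C = 7, N = 1, O = 8, P = 1)`.  Allowed symbols are the
#'   names of [coherent_b].
#' @param volume Molecular volume in cubic Angstrom; must be positive.
#' @param n_exchangeable Number of labile hydrogens (default 0); cannot
#'   exceed the total H + D count.
#' @return An object of class `"molecular_fragment"`.
#' @examples
#' d2o <- molecular_fragment("D2O", c(D = 2, O = 1), volume = 30)
#' fragment_sld(d2o)
#' @export
molecular_fragment <- function(name, formula, volume, n_exchangeable = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  formula <- unlist(formula)
  if (length(formula) && is.null(names(formula))) {
    stop("'formula' must be a named vector of atom counts")
  }
  unknown <- setdiff(names(formula), names(coherent_b))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(formula < 0)) stop("atom counts must be non-negative")
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("'volume' must be a single positive number (Angstrom^3)")
  }
  n_hd <- sum(formula[names(formula) %in% c("H", "D")])
  if (n_exchangeable < 0 || n_exchangeable > n_hd) {
    stop("'n_exchangeable' must lie in [0, total H + D count]")
  }
  structure(
    list(name = name, formula = formula, volume = volume,
         n_exchangeable = n_exchangeable),
    class = "molecular_fragment"
  )
}

#' @export
print.molecular_fragment <- function(x, ...) {
  f <- x$formula[x$formula > 0]
  cat(sprintf("<molecular_fragment> %s: %s, V = %g A^3, %d exchangeable H\n",
              x$name,
              paste0(names(f), ifelse(f == 1, "", f), collapse = ""),
              x$volume, x$n_exchangeable))
  invisible(x)
}

#' Total coherent scattering length of a fragment
#'
#' @param fragment A [molecular_fragment].
#' @return Sum of atom-count-weighted coherent scattering lengths, in fm.
#' @export
fragment_scattering_length <- function(fragment) {
  stopifnot(inherits(fragment, "molecular_fragment"))
  f <- fragment$formula
  if (!length(f)) return(0)
  sum(f * coherent_b[names(f)])
}

# fm -> 1e-6 A^-2 given volume in A^3: b[fm] * 1e-5 A / V[A^3] * 1e6
.sld_units <- function(b_fm, volume) 10 * b_fm / volume

#' Scattering length density of a fragment
#'
#' SLD is the total coherent scattering length divided by the molecular
#' volume, reported in the conventional units of 1e-6 per square Angstrom.
#'
#' @inheritParams fragment_scattering_length
#' @return SLD in 1e-6 A^-2.
#' @export
fragment_sld <- function(fragment) {
  stopifnot(inherits(fragment, "molecular_fragment"))
  .sld_units(fragment_scattering_length(fragment), fragment$volume)
}

# Both isotopologues assigned the same 30.0 A^3 molecular volume.
.water_volume <- 30.0

.sld_h2o <- function() .sld_units(2 * coherent_b[["H"]] + coherent_b[["O"]],
                                  .water_volume)
.sld_d2o <- function() .sld_units(2 * coherent_b[["D"]] + coherent_b[["O"]],
                                  .water_volume)

#' SLD of an H2O/D2O mixture
#'
#' Linear volume-fraction interpolation between the pure H2O and pure D2O
#' endpoints (-0.558 and 6.382 in 1e-6 A^-2 at a 30.0 A^3 molecular
#' volume).
#'
#' @param d2o_fraction Volume fraction of D2O, in `[0, 1]`.
#' @return SLD in 1e-6 A^-2.
#' @export
water_sld <- function(d2o_fraction) {
  if (any(!is.finite(d2o_fraction)) ||
      any(d2o_fraction < 0) || any(d2o_fraction > 1)) {
    stop("'d2o_fraction' must lie in [0, 1]")
  }
  (1 - d2o_fraction) * .sld_h2o() + d2o_fraction * .sld_d2o()
}

#' Solvent-exchanged SLD
#'
#' Headgroup SLD depends on the solvent because labile protons equilibrate
#' with the water's H/D ratio.  Given the two pure-solvent endpoints this
#' is a linear interpolation in D2O volume fraction.
#'
#' @param sld_h2o,sld_d2o SLD endpoints in pure H2O and pure D2O.
#' @param d2o_fraction Volume fraction of D2O, in `[0, 1]`.
#' @return Interpolated SLD, same units as the endpoints.
#' @export
exchanged_sld <- function(sld_h2o, sld_d2o, d2o_fraction) {
  if (any(!is.finite(sld_h2o)) || any(!is.finite(sld_d2o))) {
    stop("SLD endpoints must be finite")
  }
  if (any(d2o_fraction < 0) || any(d2o_fraction > 1)) {
    stop("'d2o_fraction' must lie in [0, 1]")
  }
  (1 - d2o_fraction) * sld_h2o + d2o_fraction * sld_d2o
}

#' Contrast specification
#'
#' One measurement solvent: its D2O volume fraction (which fixes the water
#' SLD) and the relative instrumental resolution used when smearing model
#' curves for that measurement.
#'
#' @param d2o_fraction Volume fraction of D2O in the subphase, `[0, 1]`.
#' @param dq_over_q Relative resolution dQ/Q (FWHM); must be positive.
#' @return An object of class `"contrast_spec"` with fields
#'   `d2o_fraction`, `water_sld` and `dq_over_q`.
#' @export
contrast_spec <- function(d2o_fraction, dq_over_q = 0.08) {
  stopifnot(length(d2o_fraction) == 1L, length(dq_over_q) == 1L)
  if (dq_over_q <= 0) stop("'dq_over_q' must be > 0")
  structure(
    list(d2o_fraction = d2o_fraction,
         water_sld = water_sld(d2o_fraction),
         dq_over_q = dq_over_q),
    class = "contrast_spec"
  )
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("<contrast_spec> %.0f%% D2O, water SLD %.3f e-6/A^2, dQ/Q %.3g\n",
              100 * x$d2o_fraction, x$water_sld, x$dq_over_q))
  invisible(x)
}

#' Lipid class composition
#'
#' Mole fractions of the three headgroup classes of an E. coli polar
#' extract: phosphatidylethanolamine (PE), phosphatidylglycerol (PG) and
#' cardiolipin (CL).  Cardiolipin counts as one molecule (four acyl
#' chains, double glycerophosphate head).
#'
#' @param x_pe,x_pg,x_cl Mole fractions; must sum to 1 within 1e-9.
#' @param deuterated Logical: per-deuterated extract (all non-labile H
#'   replaced by D)?
#' @return An object of class `"lipid_composition"`.
#' @export
lipid_composition <- function(x_pe = 0.75, x_pg = 0.13, x_cl = 0.12,
                              deuterated = FALSE) {
  x <- c(PE = x_pe, PG = x_pg, CL = x_cl)
  if (any(x < 0) || any(x > 1)) stop("mole fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1")
  structure(list(fractions = x, deuterated = isTRUE(deuterated)),
            class = "lipid_composition")
}

#' @export
print.lipid_composition <- function(x, ...) {
  cat(sprintf("<lipid_composition> PE %.0f%% / PG %.0f%% / CL %.0f%%%s\n",
              100 * x$fractions[["PE"]], 100 * x$fractions[["PG"]],
              100 * x$fractions[["CL"]],
              if (x$deuterated) " (per-deuterated)" else ""))
  invisible(x)
}

#' Read a lipid fragment library
#'
#' The library is a plain tab-separated table with one row per fragment
#' and columns `name`, `class`, `region` (`head`/`tail`), the atom counts
#' `H D C N O P`, `volume` (A^3) and `n_exchangeable`.  The file shipped
#' with the package (`system.file("extdata", "fragments_ecoli.tsv",
#' package = "slabnr")`) covers the PE/PG/CL classes; users can supply
#' their own file to add classes without code changes.
#'
#' @param path Path to the table; defaults to the bundled library.
#' @return Named list of lists, one per class, each with `head` and
#'   `tail` [molecular_fragment]s.
#' @export
read_fragment_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fragments_ecoli.tsv", package = "slabnr")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("fragment library not found: ", path)
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "class", "region", "H", "D", "C", "N", "O", "P",
            "volume", "n_exchangeable")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("fragment library lacks column(s): ", paste(missing, collapse = ", "))
  }
  lib <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    frag <- molecular_fragment(
      row$name,
      c(H = row$H, D = row$D, C = row$C, N = row$N, O = row$O, P = row$P),
      volume = row$volume,
      n_exchangeable = row$n_exchangeable
    )
    lib[[row$class]][[row$region]] <- frag
  }
  lib
}

# swap all non-labile H for D (per-deuteration); labile H stay H and are
# handled by solvent exchange
.deuterate <- function(fragment) {
  f <- fragment$formula
  nH <- if ("H" %in% names(f)) f[["H"]] else 0
  swap <- max(0, nH - fragment$n_exchangeable)
  if (swap > 0) {
    f[["H"]] <- nH - swap
    f[["D"]] <- (if ("D" %in% names(f)) f[["D"]] else 0) + swap
  }
  fragment$formula <- f
  fragment
}

# scattering length (fm) with the fragment's labile hydrogens replaced by
# the solvent H/D ratio (D occupancy = D2O volume fraction)
.exchanged_b <- function(fragment, d2o_fraction) {
  b <- fragment_scattering_length(fragment)
  n <- fragment$n_exchangeable
  if (n == 0) return(b)
  # labile sites are stored as H in the formula
  b + n * d2o_fraction * (coherent_b[["D"]] - coherent_b[["H"]])
}

#' Composition-weighted head and tail SLDs
#'
#' Mole-fraction-weighted SLDs of the headgroup and acyl-tail regions of a
#' lipid mixture: sums of per-class scattering lengths divided by sums of
#' per-class volumes.  Headgroup labile hydrogens take the solvent H/D
#' ratio; tails do not exchange.  A per-deuterated composition swaps every
#' non-labile H for D before the sums.
#'
#' @param composition A [lipid_composition].
#' @param contrast A [contrast_spec] (or a bare D2O fraction).
#' @param fragments Fragment library as returned by
#'   [read_fragment_library()].
#' @return Named numeric vector `c(head = ..., tail = ...)` in 1e-6 A^-2.
#' @export
mixture_region_slds <- function(composition, contrast,
                                fragments = read_fragment_library()) {
  stopifnot(inherits(composition, "lipid_composition"))
  if (inherits(contrast, "contrast_spec")) {
    f_d2o <- contrast$d2o_fraction
  } else {
    f_d2o <- contrast
    if (f_d2o < 0 || f_d2o > 1) stop("'contrast' must lie in [0, 1]")
  }
  x <- composition$fractions
  active <- names(x)[x > 0]
  missing <- active[!vapply(active, function(cl) {
    !is.null(fragments[[cl]]$head) && !is.null(fragments[[cl]]$tail)
  }, logical(1))]
  if (length(missing)) {
    stop("no head/tail fragments for class(es): ",
         paste(missing, collapse = ", "))
  }
  b_head <- v_head <- b_tail <- v_tail <- 0
  for (cl in active) {
    head <- fragments[[cl]]$head
    tail <- fragments[[cl]]$tail
    if (composition$deuterated) {
      head <- .deuterate(head)
      tail <- .deuterate(tail)
    }
    b_head <- b_head + x[[cl]] * .exchanged_b(head, f_d2o)
    v_head <- v_head + x[[cl]] * head$volume
    b_tail <- b_tail + x[[cl]] * fragment_scattering_length(tail)
    v_tail <- v_tail + x[[cl]] * tail$volume
  }
  c(head = .sld_units(b_head, v_head), tail = .sld_units(b_tail, v_tail))
}
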