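#' Reflectivity curve container
#'
#' A single contrast's measured (or simulated) specular reflectivity:
#' Q in A^-1 strictly increasing and positive, R dimensionless, optional
#' 1-sigma uncertainty dR and resolution width dQ (FWHM).
#'
#' @param q,r,dr,dq Numeric vectors (dr, dq optional).
#' @param contrast Optional [contrast_spec] attached as an attribute.
#' @return A data frame of class `"reflectivity_curve"`.
#' @export
reflectivity_curve <- function(q, r, dr = NULL, dq = NULL, contrast = NULL) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("Q must be finite and > 0")
  if (is.unsorted(q, strictly = TRUE)) stop("Q must be strictly increasing")
  if (any(r < 0)) stop("R must be >= 0")
  if (!is.null(dr) && any(dr <= 0)) stop("dR must be > 0 where present")
  out <- data.frame(q = q, r = r)
  if (!is.null(dr)) out$dr <- dr
  if (!is.null(dq)) out$dq <- dq
  class(out) <- c("reflectivity_curve", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

#' @export
print.reflectivity_curve <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<reflectivity_curve> %d points, Q %.4g-%.4g A^-1%s\n",
              nrow(x), min(x$q), max(x$q),
              if (!is.null(ct)) sprintf(", %.0f%% D2O",
                                        100 * ct$d2o_fraction) else ""))
  invisible(x)
}

#' Time-of-flight instrument specification
#'
#' Describes the Q coverage and noise of a time-of-flight reflectometer
#' running at fixed angles over a wavelength band: `Q = 4 pi sin(theta) /
#' lambda`, so the accessible range is the union over angles of
#' `[4 pi sin(theta)/lambda_max, 4 pi sin(theta)/lambda_min]`.
#'
#' @param wavelength Wavelength band `c(min, max)` in A.
#' @param angles Incidence angles in degrees.
#' @param dq_over_q Relative resolution (FWHM), dimensionless.
#' @param points_per_decade Density of the logarithmic Q grid.
#' @param sigma_rel Relative Gaussian counting noise on R.
#' @param background Constant additive background.
#' @param q_min,q_max Optional clip of the simulated Q range, A^-1.
#' @return An object of class `"instrument_spec"`.
#' @export
instrument_spec <- function(wavelength = c(2, 30),
                            angles = c(0.624, 3.78),
                            dq_over_q = 0.08,
                            points_per_decade = 40,
                            sigma_rel = 0.03,
                            background = 1e-7,
                            q_min = NULL, q_max = NULL) {
  wavelength <- as.numeric(unlist(wavelength))
  angles <- as.numeric(unlist(angles))
  stopifnot(length(wavelength) == 2L)
  if (wavelength[1] >= wavelength[2]) stop("need wavelength min < max")
  if (any(angles <= 0)) stop("angles must be > 0")
  if (dq_over_q <= 0) stop("'dq_over_q' must be > 0")
  structure(list(wavelength = wavelength, angles = angles,
                 dq_over_q = dq_over_q,
                 points_per_decade = points_per_decade,
                 sigma_rel = sigma_rel, background = background,
                 q_min = q_min, q_max = q_max),
            class = "instrument_spec")
}

#' FIGARO-like and D17-like instrument presets
#'
#' Horizontal (`instrument_figaro`) and vertical (`instrument_d17`)
#' time-of-flight reflectometer geometries: a 2-30 A wavelength band at
#' two incidence angles (0.624/3.78 and 0.8/3.2 degrees respectively).
#' The FIGARO preset clips the simulated range to 0.005-0.3 A^-1, the
#' well-measured region for solid-liquid cells.
#'
#' @param ... Overrides passed on to [instrument_spec()].
#' @return An [instrument_spec].
#' @export
instrument_figaro <- function(...) {
  args <- utils::modifyList(
    list(angles = c(0.624, 3.78), q_min = 0.005, q_max = 0.3), list(...))
  do.call(instrument_spec, args)
}

#' @rdname instrument_figaro
#' @export
instrument_d17 <- function(...) {
  args <- utils::modifyList(list(angles = c(0.8, 3.2)), list(...))
  do.call(instrument_spec, args)
}

#' Logarithmic Q grid of a time-of-flight measurement
#'
#' @param spec An [instrument_spec].
#' @return Data frame with columns `q` (A^-1, log-spaced over the union
#'   of the per-angle ranges, clipped to `q_min`/`q_max` if set) and `dq`
#'   (`dq_over_q * q`, FWHM).
#' @export
make_q_grid <- function(spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  th <- spec$angles * pi / 180
  lo <- min(4 * pi * sin(th) / spec$wavelength[2])
  hi <- max(4 * pi * sin(th) / spec$wavelength[1])
  if (!is.null(spec$q_min)) lo <- max(lo, spec$q_min)
  if (!is.null(spec$q_max)) hi <- min(hi, spec$q_max)
  if (lo >= hi) stop("empty Q range")
  n <- max(2L, ceiling(spec$points_per_decade * log10(hi / lo)) + 1L)
  q <- 10^seq(log10(lo), log10(hi), length.out = n)
  data.frame(q = q, dq = spec$dq_over_q * q)
}

#' Simulate a contrast-variation reflectivity series
#'
#' Generates one synthetic time-of-flight dataset per water contrast from
#' a ground-truth bilayer model: exact Abeles curve, Gaussian resolution
#' smearing, multiplicative Gaussian counting noise `R (1 + eps)` with
#' `eps ~ N(0, sigma_rel)`, and a constant additive background.  Quoted
#' uncertainties are `dR = sigma_rel R + background`.  Fully
#' deterministic for a given seed.
#'
#' @param model Ground-truth [slb_model] (its `init` values are the
#'   truth).
#' @param d2o_fractions D2O volume fractions of the contrasts (default:
#'   the four-contrast series H2O, 40%, 60%, 100% D2O).
#' @param instrument An [instrument_spec]; default [instrument_figaro()].
#' @param seed Integer seed.
#' @return Named list of [reflectivity_curve]s, one per contrast, with
#'   the truth parameter vector in the `"truth"` attribute.
#' @examples
#' truth <- ground_truth_presets()[["hEcoli_50C"]]
#' data <- simulate_contrast_series(truth, seed = 7)
#' @export
simulate_contrast_series <- function(model,
                                     d2o_fractions = c(0, 0.4, 0.6, 1),
                                     instrument = instrument_figaro(),
                                     seed = 1) {
  stopifnot(inherits(model, "slb_model"))
  grid <- make_q_grid(instrument)
  set.seed(seed)
  out <- list()
  for (f in d2o_fractions) {
    ct <- contrast_spec(f, instrument$dq_over_q)
    st <- build_slab_stack(model, contrast = ct)
    r_sm <- smear_reflectivity(
      grid$q, function(qq) abeles_reflectivity(st, ct$water_sld, qq),
      instrument$dq_over_q)
    eps <- stats::rnorm(length(r_sm), 0, instrument$sigma_rel)
    r_obs <- pmax(r_sm * (1 + eps) + instrument$background, 0)
    dr <- instrument$sigma_rel * r_sm + instrument$background
    if (all(dr <= 0)) dr <- NULL  # noise-free: no meaningful uncertainty
    nm <- if (f == 0) "H2O" else if (f == 1) "D2O" else
      sprintf("D2O_%02.0f", 100 * f)
    out[[nm]] <- reflectivity_curve(grid$q, r_obs, dr, grid$dq, contrast = ct)
  }
  attr(out, "truth") <- .par_vector(model)
  attr(out, "instrument") <- instrument
  out
}

#' Ground-truth structural presets
#'
#' The three fitted supported-lipid-bilayer structures used as synthetic
#' ground truths, as [slb_model]s whose `init` values are the truth:
#'
#' * `hEcoli_50C` — hydrogenated extract deposited at 50 C: symmetric
#'   three-layer bilayer (water gap 8 A; heads 7 A; tails 27 A, 12%
#'   solvent; roughness 4 A; head SLD 1.55/2.16 in H2O/D2O, tail -0.55).
#' * `dEcoli_50C` — per-deuterated extract deposited at 50 C: one-layer
#'   bilayer (water gap 9 A; bilayer 41 A, 6% solvent, SLD 6.66,
#'   roughness 7 A) plus a sparse vesicle extension (14 A water gap, 4%
#'   coverage) present in the H2O contrast only.
#' * `dEcoli_25C` — per-deuterated extract deposited at 25 C: as above
#'   but water gap 6 A, bilayer 42 A with 3% solvent, SLD 6.60, 3%
#'   vesicle coverage retained in all contrasts.
#'
#' @return Named list of [slb_model]s.
#' @export
ground_truth_presets <- function() {
  list(
    hEcoli_50C = slb_model(
      "three_layer",
      params = list(d_water = 8, d_head = 7, d_tail = 27,
                    phi_tail = 0.12, sigma = 4),
      sld = list(head_h2o = 1.55, head_d2o = 2.16, tail = -0.55)
    ),
    dEcoli_50C = slb_model(
      "one_layer_vesicles",
      params = list(d_water = 9, d_bilayer = 41, phi_bilayer = 0.06,
                    sigma = 7, d_vwater = 14, coverage = 0.04,
                    sigma_ves = 10),
      sld = list(bilayer = 6.66),
      vesicles_in = "h2o_only"
    ),
    dEcoli_25C = slb_model(
      "one_layer_vesicles",
      params = list(d_water = 6, d_bilayer = 42, phi_bilayer = 0.03,
                    sigma = 7, d_vwater = 14, coverage = 0.03,
                    sigma_ves = 10),
      sld = list(bilayer = 6.60),
      vesicles_in = "all"
    )
  )
}
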