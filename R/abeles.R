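#' Specular reflectivity of a slab stack (Abeles optical matrix method)
#'
#' Exact specular reflectivity of a stratified solid-liquid interface.
#' For each momentum transfer Q (defined in the fronting medium) the
#' perpendicular wavevector in layer n is
#' `k_n = sqrt((Q/2)^2 - 4 pi (rho_n - rho_fronting))`, taken on the
#' complex branch in evanescent regions.  Interface Fresnel coefficients
#' are damped by the Nevot-Croce factor
#' `exp(-2 k_n k_{n+1} sigma^2)` and combined through the characteristic
#' matrix product; the result is clipped to at most 1.
#'
#' @param stack A [slab_stack].
#' @param solvent_sld Backing (solvent) SLD in 1e-6 A^-2.
#' @param q Vector of momentum transfer values, A^-1, all positive.
#' @return Numeric vector of reflectivities in `[0, 1]`.
#' @export
abeles_reflectivity <- function(stack, solvent_sld, q) {
  stopifnot(inherits(stack, "slab_stack"))
  if (any(!is.finite(q)) || any(q <= 0)) stop("'q' must be finite and > 0")
  sld <- stack$sld
  sld[nrow(stack)] <- solvent_sld
  rho <- vapply(seq_len(nrow(stack)), function(i) {
    phi <- stack$solvent_fraction[i]
    phi * solvent_sld + (1 - phi) * sld[i]
  }, numeric(1))
  if (any(!is.finite(rho)) || any(!is.finite(stack$d)) ||
      any(!is.finite(stack$roughness))) {
    stop("non-finite stack parameters")
  }
  .abeles(q, d = stack$d, rho = rho, sigma = stack$roughness)
}

# d/rho/sigma indexed fronting..backing, rho in 1e-6 A^-2, sigma[j] =
# roughness of the interface between layer j-1 and j; compiled kernel
.abeles <- function(q, d, rho, sigma) {
  abeles_kernel(as.numeric(q), as.numeric(d), as.numeric(rho),
                as.numeric(sigma))
}

#' Gaussian resolution smearing
#'
#' Convolves an exact model curve with the instrument resolution: at each
#' Q the model is averaged over a Gaussian of width
#' `sigma_Q = dq_over_q * Q / 2.355` (FWHM-to-sigma), evaluated by
#' oversampled quadrature over +/- 3.5 sigma.
#'
#' @param q Q grid (A^-1) on which the smeared curve is wanted.
#' @param r_fun Function `function(q) R(q)` returning the exact curve,
#'   e.g. a closure over [abeles_reflectivity()].
#' @param dq_over_q Relative FWHM resolution; `0` returns `r_fun(q)`
#'   unchanged.
#' @param n_nodes Odd number of quadrature nodes (default 21).
#' @return Smeared reflectivity at `q`.
#' @export
smear_reflectivity <- function(q, r_fun, dq_over_q, n_nodes = 21) {
  if (dq_over_q < 0) stop("'dq_over_q' must be >= 0")
  if (dq_over_q == 0) return(r_fun(q))
  if (n_nodes < 21) n_nodes <- 21
  if (n_nodes %% 2 == 0) n_nodes <- n_nodes + 1
  g <- seq(-3.5, 3.5, length.out = n_nodes)
  w <- exp(-g^2 / 2)
  w <- w / sum(w)
  sigma <- dq_over_q * q / 2.355
  nodes <- outer(q, rep(1, n_nodes)) + outer(sigma, g)
  nodes[nodes <= 0] <- min(q) * 1e-3  # guard: Q must stay positive
  rv <- matrix(r_fun(as.vector(nodes)), nrow = length(q))
  as.vector(rv %*% w)
}

#' Smeared model reflectivity of a stack
#'
#' Convenience wrapper: exact Abeles curve plus Gaussian resolution
#' smearing and an optional constant incoherent background.
#'
#' @inheritParams abeles_reflectivity
#' @param dq_over_q Relative FWHM resolution (0 = no smearing).
#' @param background Constant additive background (default 0).
#' @return Numeric vector of smeared reflectivities.
#' @export
model_reflectivity <- function(stack, solvent_sld, q, dq_over_q = 0,
                               background = 0) {
  r <- smear_reflectivity(
    q, function(qq) abeles_reflectivity(stack, solvent_sld, qq), dq_over_q)
  r + background
}
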