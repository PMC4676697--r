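# Independent Parratt-recursion reflectivity, coded separately from the
# package's Abeles matrix kernel.  Scalar recursion from the backing
# upwards; same layer conventions (vectors fronting..backing, rho in
# 1e-6 A^-2, sigma[j] = roughness of the interface between j-1 and j).
parratt_reflectivity <- function(q, d, rho, sigma) {
  m <- length(rho)
  vapply(q, function(qq) {
    k <- sqrt(as.complex((qq / 2)^2 - 4 * pi * (rho - rho[1]) * 1e-6))
    r <- (k[m - 1] - k[m]) / (k[m - 1] + k[m]) *
      exp(-2 * k[m - 1] * k[m] * sigma[m]^2)
    if (m > 2) {
      for (j in (m - 2):1) {
        f <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
          exp(-2 * k[j] * k[j + 1] * sigma[j + 1]^2)
        ph <- exp(2i * k[j + 1] * d[j + 1])
        r <- (f + r * ph) / (1 + f * r * ph)
      }
    }
    Mod(r)^2
  }, numeric(1))
}

# effective (solvent-mixed) layer vectors of a slab_stack
stack_vectors <- function(stack, solvent_sld) {
  sld <- stack$sld
  sld[nrow(stack)] <- solvent_sld
  rho <- stack$solvent_fraction * solvent_sld +
    (1 - stack$solvent_fraction) * sld
  list(d = stack$d, rho = rho, sigma = stack$roughness)
}

# random physical stack with up to `max_layers` slabs
random_stack <- function(max_layers = 4) {
  n <- sample.int(max_layers, 1)
  slabs <- lapply(seq_len(n), function(i) {
    slab(d = stats::runif(1, 5, 300),
         sld = stats::runif(1, -0.5, 7),
         solvent_fraction = stats::runif(1),
         roughness = stats::runif(1, 0, 6),
         name = paste0("L", i))
  })
  suppressWarnings(slab_stack(slabs, fronting_sld = 2.07,
                              backing_roughness = stats::runif(1, 0, 6)))
}

# cheap instrument for fitting tests: coarse grid, same physics
test_instrument <- function(...) {
  instrument_figaro(points_per_decade = 15, ...)
}
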