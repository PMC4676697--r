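make_noiseless <- function(preset = "hEcoli_50C", ppd = 12) {
  truth <- ground_truth_presets()[[preset]]
  truth$background <- 0  # keep model and noise-free data consistent
  data <- simulate_contrast_series(
    truth, instrument = test_instrument(sigma_rel = 0, background = 0,
                                        points_per_decade = ppd),
    seed = 1)
  list(truth = truth, data = data)
}

test_that("chi-square matches its definition", {
  nl <- make_noiseless()
  # model curve equals data exactly -> 0 (background-free, noise-free)
  m0 <- nl$truth
  m0$background <- 0
  expect_equal(as.numeric(chi_square(m0, NULL, nl$data)), 0,
               tolerance = 1e-12)
  # a single point with a 2-sigma residual contributes 4
  curve <- nl$data[[1]][10, ]
  one <- reflectivity_curve(curve$q, curve$r + 2 * 0.05 * curve$r,
                            dr = 0.05 * curve$r,
                            contrast = attr(nl$data[[1]], "contrast"))
  expect_equal(as.numeric(chi_square(m0, NULL, list(one))), 4,
               tolerance = 1e-6)
  # without dR the weight defaults to 5% of the observation
  one_nodr <- reflectivity_curve(curve$q, curve$r * 1.10,
                                 contrast = attr(nl$data[[1]], "contrast"))
  expect_equal(as.numeric(chi_square(m0, NULL, list(one_nodr))),
               (0.10 / 0.05 / 1.10)^2, tolerance = 1e-6)
})

test_that("the truth is a local minimum of the objective", {
  nl <- make_noiseless()
  m0 <- nl$truth
  m0$background <- 0
  chi0 <- as.numeric(chi_square(m0, NULL, nl$data))
  for (pn in c("d_head", "d_tail", "phi_tail", "d_water", "sigma")) {
    for (delta in c(-0.03, 0.03)) {
      p <- slabnr:::.par_vector(m0)
      p[pn] <- p[pn] * (1 + delta)
      expect_gt(as.numeric(chi_square(m0, p, nl$data)), chi0)
    }
  }
})

test_that("objective is invariant under dataset ordering", {
  nl <- make_noiseless()
  x1 <- chi_square(nl$truth, NULL, nl$data)
  x2 <- chi_square(nl$truth, NULL, rev(nl$data))
  expect_equal(as.numeric(x1), as.numeric(x2), tolerance = 1e-14)
  f1 <- nr_corefine(nl$truth, nl$data, n_starts = 1, seed = 5)
  f2 <- nr_corefine(nl$truth, rev(nl$data), n_starts = 1, seed = 5)
  expect_identical(coef(f1), coef(f2))
})

test_that("starting at the truth returns the truth on noiseless data", {
  nl <- make_noiseless()
  m0 <- nl$truth
  m0$background <- 0
  fit <- nr_corefine(m0, nl$data, n_starts = 1, seed = 1)
  expect_lt(fit$chisq_total, 1e-10)
  truth <- attr(nl$data, "truth")
  expect_equal(coef(fit), truth[fit$free], tolerance = 1e-4)
})

test_that("co-refinement recovers the truth from jittered starts (noiseless)", {
  nl <- make_noiseless()
  fit <- nr_corefine(nl$truth, nl$data, n_starts = 4, seed = 2)
  truth <- attr(nl$data, "truth")
  for (pn in c("d_head", "d_tail", "phi_tail")) {
    expect_lt(abs(coef(fit)[[pn]] - truth[[pn]]) / truth[[pn]], 0.02)
  }
  # global chi2 is the sum of the per-contrast terms
  expect_equal(sum(fit$chisq), fit$chisq_total, tolerance = 1e-12)
  # bounds are always respected
  tab <- fit$par_table
  expect_true(all(tab$fitted >= tab$min & tab$fitted <= tab$max))
})

test_that("fits are deterministic given the seed", {
  nl <- make_noiseless(ppd = 8)
  f1 <- nr_corefine(nl$truth, nl$data, n_starts = 3, seed = 9)
  f2 <- nr_corefine(nl$truth, nl$data, n_starts = 3, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chisq_total, f2$chisq_total)
  expect_identical(f1$starts_par, f2$starts_par)
})

test_that("contrast variation tightens the tail-solvent constraint", {
  # the same structure fitted against one contrast admits a much wider
  # tail-hydration confidence range than the four-contrast co-refinement
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  data4 <- simulate_contrast_series(
    truth, instrument = test_instrument(), seed = 21)
  width <- function(data) {
    fit <- nr_corefine(truth, data, n_starts = 1, seed = 3)
    ci <- estimate_uncertainty(fit, method = "profile", parm = "phi_tail")
    ci["phi_tail", "upper"] - ci["phi_tail", "lower"]
  }
  expect_gt(width(data4["D2O"]), width(data4))
})

test_that("a fit with zero varied parameters is a forward evaluation", {
  nl <- make_noiseless()
  frozen <- nl$truth
  frozen$params$vary <- FALSE
  fit <- nr_corefine(frozen, nl$data)
  expect_identical(fit$free, character(0))
  expect_identical(fit$n_free, 0L)
  expect_true(is.finite(fit$chisq_total))
  expect_identical(coef(fit, all = TRUE), slabnr:::.par_vector(frozen))
})

test_that("uncertainty intervals behave like errors bars should", {
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  data <- simulate_contrast_series(truth, seed = 4)
  fit <- nr_corefine(truth, data, n_starts = 2, seed = 1)
  ci <- estimate_uncertainty(fit, n_boot = 12, seed = 8)
  expect_identical(rownames(ci), fit$free)
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  # tail thickness interval of the right order (about an Angstrom)
  w_dt <- ci["d_tail", "upper"] - ci["d_tail", "lower"]
  expect_gt(w_dt, 0.05)
  expect_lt(w_dt, 4)
  # near-noiseless data collapse the intervals
  nl <- make_noiseless()
  fit0 <- nr_corefine(nl$truth, nl$data, n_starts = 1, seed = 1)
  ci0 <- estimate_uncertainty(fit0, n_boot = 8, seed = 8)
  expect_lt(max(ci0[, "upper"] - ci0[, "lower"]), 0.05)
  expect_error(estimate_uncertainty(nr_corefine(
    nl$truth, nl$data, n_starts = 1, seed = 1) |>
      (\(f) { f$free <- character(0); f })(), n_boot = 2), "free parameters")
})

test_that("profile intervals widen with the noise level", {
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  width_dt <- vapply(c(0.03, 0.06), function(s) {
    data <- simulate_contrast_series(
      truth, instrument = test_instrument(sigma_rel = s), seed = 13)
    fit <- nr_corefine(truth, data, n_starts = 1, seed = 1)
    ci <- estimate_uncertainty(fit, method = "profile", parm = "d_tail")
    ci["d_tail", "upper"] - ci["d_tail", "lower"]
  }, numeric(1))
  expect_gte(width_dt[2], width_dt[1])
})

test_that("model comparison re-enacts the vesicle-extension decision", {
  truth <- ground_truth_presets()[["dEcoli_50C"]]
  data <- simulate_contrast_series(truth, instrument = test_instrument(),
                                   seed = 6)
  with_ves <- nr_corefine(truth, data, n_starts = 4, seed = 2)
  plain <- slb_model("one_layer_vesicles", vesicles_in = "none",
                     sld = list(bilayer = 6.66),
                     params = list(d_water = 9, d_bilayer = 41,
                                   phi_bilayer = 0.06, sigma = 7))
  without <- nr_corefine(plain, data, n_starts = 4, seed = 2)
  cmp <- compare_models(without, with_ves)
  expect_identical(cmp$preferred, "b")
  expect_true(cmp$necessary)
  # identical fits tie with zero per-point improvement
  cmp_tie <- compare_models(with_ves, with_ves)
  expect_equal(cmp_tie$delta_per_point, 0)
  expect_equal(unname(diff(cmp_tie$reduced_chisq)), 0)
  # mismatched datasets are rejected
  other <- simulate_contrast_series(truth, instrument = test_instrument(),
                                    seed = 7)
  expect_error(compare_models(with_ves,
                              nr_corefine(truth, other, n_starts = 1,
                                          seed = 1)),
               "identical datasets")
})

test_that("the vesicle extension vanishes on vesicle-free truth data", {
  clean_truth <- slb_model("one_layer_vesicles", vesicles_in = "none",
                           sld = list(bilayer = 6.66),
                           params = list(d_water = 9, d_bilayer = 41,
                                         phi_bilayer = 0.06, sigma = 7))
  data <- simulate_contrast_series(clean_truth,
                                   instrument = test_instrument(), seed = 15)
  ext <- slb_model("one_layer_vesicles", vesicles_in = "h2o_only",
                   sld = list(bilayer = 6.66),
                   params = list(d_water = 9, d_bilayer = 41,
                                 phi_bilayer = 0.06, sigma = 7,
                                 coverage = list(init = 0.04)))
  fit_ext <- nr_corefine(ext, data, n_starts = 4, seed = 2)
  fit_plain <- nr_corefine(clean_truth, data, n_starts = 4, seed = 2)
  expect_lt(coef(fit_ext)[["coverage"]], 0.01)
  cmp <- compare_models(fit_plain, fit_ext)
  expect_false(cmp$necessary)
})

test_that("fit methods expose curves, residuals and predictions", {
  nl <- make_noiseless()
  fit <- nr_corefine(nl$truth, nl$data, n_starts = 1, seed = 1)
  expect_s3_class(summary(fit), "summary.slb_fit")
  expect_output(print(summary(fit)), "TOTAL")
  res <- residuals(fit)
  expect_named(res, names(fit$data))
  pr <- predict(fit, contrast = "D2O")
  expect_equal(pr, fit$curves[["D2O"]]$r_model, tolerance = 1e-12)
  pr2 <- predict(fit, q = c(0.01, 0.05), contrast = contrast_spec(0.75))
  expect_length(pr2, 2)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_named(sims[[1]], names(fit$data))
  grDevices::pdf(NULL)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
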