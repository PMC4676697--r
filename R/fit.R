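#' Multi-contrast chi-square objective
#'
#' Sum over contrasts and Q points of squared error-weighted residuals
#' between the smeared model curve and the data.  Datasets without a dR
#' column are weighted by 5 percent of the observed reflectivity.  A
#' violated equal-area constraint adds a smooth quadratic penalty instead
#' of failing, and a model-evaluation failure returns `Inf` with the
#' `"failed"` attribute set.
#'
#' @param model An [slb_model].
#' @param par Named parameter vector (full or partial; defaults filled
#'   from the model).
#' @param data Named list of [reflectivity_curve]s, each carrying a
#'   `contrast` attribute.
#' @return Total chi-square (numeric scalar) with attribute
#'   `"per_contrast"`.
#' @export
chi_square <- function(model, par = NULL, data) {
  cache <- .build_cache(data)
  p <- .par_vector(model, par)
  per <- vapply(cache, function(cc) {
    tryCatch(.contrast_chisq(model, p, cc),
             error = function(e) structure(Inf,
                                           failed = conditionMessage(e)))
  }, numeric(1))
  total <- sum(per)
  attr(total, "per_contrast") <- per
  total
}

# precomputed per-dataset pieces reused across objective evaluations:
# contrast, smearing quadrature nodes/weights, error weights, observations
.build_cache <- function(data) {
  lapply(data, function(curve) {
    ct <- attr(curve, "contrast")
    if (is.null(ct)) stop("dataset lacks a contrast_spec attribute")
    dqq <- if (!is.null(curve$dq)) stats::median(curve$dq / curve$q) else
      ct$dq_over_q
    list(ct = ct, pre = .smear_pre(curve$q, dqq),
         w = if (!is.null(curve$dr)) curve$dr else 0.05 * curve$r,
         r_obs = curve$r)
  })
}

.smear_pre <- function(q, dqq, n_nodes = 21) {
  if (dqq <= 0) return(list(nodes = q, gw = NULL, nq = length(q)))
  g <- seq(-3.5, 3.5, length.out = n_nodes)
  gw <- exp(-g^2 / 2)
  gw <- gw / sum(gw)
  sigma <- dqq * q / 2.355
  nodes <- as.vector(outer(q, rep(1, n_nodes)) + outer(sigma, g))
  nodes[nodes <= 0] <- min(q) * 1e-3
  list(nodes = nodes, gw = gw, nq = length(q))
}

# model curve on a cached grid: Abeles at the quadrature nodes, Gaussian
# resolution average, constant background
.cached_model_r <- function(model, p, cc) {
  lv <- .layer_vectors(model, p, cc$ct)
  r <- .abeles(cc$pre$nodes, lv$d, lv$rho, lv$sigma)
  if (!is.null(cc$pre$gw)) {
    r <- as.vector(matrix(r, nrow = cc$pre$nq) %*% cc$pre$gw)
  }
  structure(r + model$background, violation = lv$violation)
}

.contrast_chisq <- function(model, p, cc) {
  r_model <- .cached_model_r(model, p, cc)
  sum(((r_model - cc$r_obs) / cc$w)^2) +
    1e6 * attr(r_model, "violation")^2
}

# bounded total objective over the free parameters, closed over the cache
.make_objective <- function(model, cache, free) {
  p0 <- .par_vector(model)
  function(x) {
    p <- p0
    p[free] <- x
    v <- tryCatch(
      sum(vapply(cache, function(cc) .contrast_chisq(model, p, cc),
                 numeric(1))),
      error = function(e) Inf)
    if (!is.finite(v)) 1e30 else v
  }
}

#' Co-refine a bilayer model against several water contrasts
#'
#' Simultaneously fits one structural parameterization to all contrast
#' datasets: structural parameters are shared, only the solvent SLD and
#' headgroup exchange differ between contrasts.  Optimisation is bounded
#' local search ([stats::nlminb()]) repeated from `n_starts`
#' initialisations (the nominal start plus seeded uniform jitter of the
#' varied parameters); the lowest-chi-square result wins, with exact ties
#' broken by lexicographic parameter order for determinism.
#'
#' @inheritParams chi_square
#' @param n_starts Number of multistart initialisations (default 8).
#' @param seed Integer seed controlling the jitter.
#' @param jitter Relative half-width of the uniform start jitter
#'   (default 0.2, i.e. +/- 20 percent).
#' @param control Control list passed to [stats::nlminb()].
#' @return An object of class `"slb_fit"`: best-fit parameter table,
#'   per-contrast and global chi-square, model curves on each dataset's
#'   Q grid, derived quantities and convergence diagnostics.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`, `confint`.
#' @examples
#' \donttest{
#' truth <- ground_truth_presets()[["hEcoli_50C"]]
#' data <- simulate_contrast_series(truth, seed = 7)
#' fit <- nr_corefine(truth, data, n_starts = 2, seed = 1)
#' summary(fit)
#' }
#' @export
nr_corefine <- function(model, data, n_starts = 8, seed = 1, jitter = 0.2,
                        control = list(iter.max = 400, eval.max = 1200)) {
  stopifnot(inherits(model, "slb_model"), length(data) >= 1)
  data <- .order_contrasts(data)
  tab <- model$params
  free <- tab$name[tab$vary]
  if (!length(free)) {
    # forward evaluation only
    return(.make_fit(model, data, .par_vector(model), n_starts = 0,
                     seed = seed, starts_info = NULL))
  }
  lower <- stats::setNames(tab$min[tab$vary], free)
  upper <- stats::setNames(tab$max[tab$vary], free)
  init <- stats::setNames(tab$init[tab$vary], free)

  obj <- .make_objective(model, .build_cache(data), free)

  set.seed(seed)
  starts <- matrix(NA_real_, nrow = n_starts, ncol = length(free),
                   dimnames = list(NULL, free))
  starts[1, ] <- init
  if (n_starts > 1) {
    for (i in 2:n_starts) {
      x <- init * (1 + stats::runif(length(free), -jitter, jitter))
      starts[i, ] <- pmin(pmax(x, lower), upper)
    }
  }
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch(
      stats::nlminb(starts[i, ], obj, lower = lower, upper = upper,
                    control = control),
      error = function(e) list(objective = Inf, par = starts[i, ],
                               convergence = 1L,
                               message = conditionMessage(e)))
  }
  ok <- vapply(results, function(r) is.finite(r$objective), logical(1))
  if (!any(ok)) {
    stop("all optimisation starts failed; last message: ",
         results[[n_starts]]$message)
  }
  objs <- vapply(results, `[[`, numeric(1), "objective")
  best <- which(objs <= min(objs) * (1 + 1e-12))
  if (length(best) > 1) {
    # deterministic tie-break: lexicographically smallest parameter vector
    pm <- do.call(rbind, lapply(results[best], `[[`, "par"))
    best <- best[do.call(order, as.data.frame(pm))[1]]
  } else {
    best <- best[1]
  }
  fitted <- pmin(pmax(results[[best]]$par, lower), upper)
  starts_info <- data.frame(
    start = seq_len(n_starts),
    objective = objs,
    converged = vapply(results, function(r)
      isTRUE(r$convergence == 0), logical(1)),
    iterations = vapply(results, function(r)
      if (!is.null(r$iterations)) r$iterations else NA_integer_, integer(1))
  )
  fit <- .make_fit(model, data, .par_vector(model, fitted), n_starts, seed,
                   starts_info, free = free)
  # per-start solutions: useful for diagnosing multimodality / identifiability
  fit$starts_par <- do.call(rbind, lapply(results, `[[`, "par"))
  fit
}

# sort datasets by D2O fraction so results cannot depend on list order
.order_contrasts <- function(data) {
  f <- vapply(data, function(d) attr(d, "contrast")$d2o_fraction, numeric(1))
  data[order(f)]  # radix order is stable: equal fractions keep input order
}

.make_fit <- function(model, data, par, n_starts, seed, starts_info,
                      free = character(0)) {
  chis <- chi_square(model, par, data)
  per <- attr(chis, "per_contrast")
  curves <- lapply(data, function(curve) {
    ct <- attr(curve, "contrast")
    st <- build_slab_stack(model, par, ct)
    dqq <- if (!is.null(curve$dq)) stats::median(curve$dq / curve$q) else
      ct$dq_over_q
    data.frame(q = curve$q,
               r_model = model_reflectivity(st, ct$water_sld, curve$q, dqq,
                                            background = model$background))
  })
  viol <- max(vapply(data, function(curve) {
    attr(build_slab_stack(model, par, attr(curve, "contrast")),
         "constraint_violation")
  }, numeric(1)))
  tab <- model$params
  tab$fitted <- par[tab$name]
  n_points <- sum(vapply(data, nrow, integer(1)))
  n_free <- length(free)
  structure(
    list(model = model, data = data, par = par, par_table = tab,
         free = free,
         chisq = per, chisq_total = as.numeric(chis),
         n_points = n_points, n_free = n_free,
         chisq_reduced = as.numeric(chis) / max(1, n_points - n_free),
         derived = derived_quantities(model, par),
         curves = curves,
         constraint_violation = viol,
         starts = starts_info, n_starts = n_starts, seed = seed),
    class = "slb_fit"
  )
}

#' @export
print.slb_fit <- function(x, ...) {
  cat(sprintf("<slb_fit> %s co-refined against %d contrast(s)\n",
              x$model$type, length(x$data)))
  cat(sprintf("  chi2 = %.4g (reduced %.4g, %d points, %d free)\n",
              x$chisq_total, x$chisq_reduced, x$n_points, x$n_free))
  if (length(x$free)) {
    print(round(x$par[x$free], 4))
  }
  invisible(x)
}

#' @export
summary.slb_fit <- function(object, ...) {
  structure(list(fit = object,
                 layers = layer_table(object$model, object$par),
                 derived = object$derived),
            class = "summary.slb_fit")
}

#' @export
print.summary.slb_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLayer structure:\n")
  print(x$layers, row.names = FALSE)
  cat("\nDerived: ",
      paste(names(x$derived), round(x$derived, 3), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat("Per-contrast chi2: ",
      paste(names(x$fit$chisq), round(x$fit$chisq, 2), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.slb_fit <- function(object, all = FALSE, ...) {
  if (all) object$par else object$par[object$free]
}

#' Predict model reflectivity from a fit
#'
#' @param object An `slb_fit`.
#' @param q Q grid (A^-1); defaults to the grid of the selected dataset.
#' @param contrast Dataset name/index, or a [contrast_spec] for an
#'   arbitrary solvent.
#' @param ... Unused.
#' @return Numeric vector of smeared model reflectivities.
#' @export
predict.slb_fit <- function(object, q = NULL, contrast = 1, ...) {
  if (inherits(contrast, "contrast_spec")) {
    ct <- contrast
    if (is.null(q)) stop("supply 'q' with an explicit contrast_spec")
    dqq <- ct$dq_over_q
  } else {
    curve <- object$data[[contrast]]
    ct <- attr(curve, "contrast")
    if (is.null(q)) q <- curve$q
    dqq <- if (!is.null(curve$dq)) stats::median(curve$dq / curve$q) else
      ct$dq_over_q
  }
  st <- build_slab_stack(object$model, object$par, ct)
  model_reflectivity(st, ct$water_sld, q, dqq,
                     background = object$model$background)
}

#' @export
residuals.slb_fit <- function(object, ...) {
  lapply(stats::setNames(names(object$data), names(object$data)),
         function(nm) {
    curve <- object$data[[nm]]
    w <- if (!is.null(curve$dr)) curve$dr else 0.05 * curve$r
    (curve$r - object$curves[[nm]]$r_model) / w
  })
}

#' @export
plot.slb_fit <- function(x, offset = 10, ...) {
  n <- length(x$data)
  cols <- grDevices::hcl.colors(max(n, 3), "Dark 3")
  fac <- offset^(seq_len(n) - 1)
  ylim <- range(unlist(lapply(seq_len(n), function(i)
    x$data[[i]]$r / fac[i])), na.rm = TRUE)
  ylim[1] <- max(ylim[1], 1e-12)
  plot(NA, xlim = range(x$data[[1]]$q), ylim = ylim, log = "xy",
       xlab = expression(Q ~ (ring(A)^-1)), ylab = "R (offset)", ...)
  for (i in seq_len(n)) {
    d <- x$data[[i]]
    graphics::points(d$q, d$r / fac[i], col = cols[i], pch = 16, cex = 0.5)
    graphics::lines(x$curves[[i]]$q, x$curves[[i]]$r_model / fac[i],
                    col = cols[i])
  }
  graphics::legend("bottomleft", legend = names(x$data), col = cols[1:n],
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate replicate datasets from a fitted structure
#'
#' Draws `nsim` synthetic replicates of the observed datasets at the
#' fitted parameters: model curve plus Gaussian noise of the quoted dR.
#'
#' @param object An `slb_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of length `nsim`; each element a named list of
#'   [reflectivity_curve]s.
#' @export
simulate.slb_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  lapply(seq_len(nsim), function(b) {
    lapply(stats::setNames(names(object$data), names(object$data)),
           function(nm) {
      curve <- object$data[[nm]]
      mu <- object$curves[[nm]]$r_model
      dr <- if (!is.null(curve$dr)) curve$dr else 0.05 * curve$r
      reflectivity_curve(curve$q, pmax(mu + stats::rnorm(length(mu), 0, dr), 0),
                         dr, curve$dq, contrast = attr(curve, "contrast"))
    })
  })
}

#' Parameter uncertainties of a co-refined fit
#'
#' Default method: residual bootstrap.  Within each contrast the
#' residuals about the best-fit curve are resampled with replacement,
#' added back to the model curve, and the model is refitted (single
#' start from the best fit); intervals are percentile intervals of the
#' bootstrap distribution.  The `"profile"` method instead scans each
#' parameter, re-optimising the others, and interpolates the
#' delta-chi-square = 1 crossings.
#'
#' @param fit A converged `slb_fit` with at least one free parameter.
#' @param method `"bootstrap"` (default) or `"profile"`.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param level Interval coverage (default 0.68, one sigma).
#' @param seed Integer seed.
#' @param parm Parameters to profile (default: all free parameters);
#'   ignored by the bootstrap, which always refits everything.
#' @return Matrix with one row per free parameter and columns `lower`,
#'   `upper` (plus `estimate`); bootstrap results also carry the draws in
#'   the `"samples"` attribute.
#' @export
estimate_uncertainty <- function(fit, method = c("bootstrap", "profile"),
                                 n_boot = 100, level = 0.68, seed = 1,
                                 parm = NULL) {
  stopifnot(inherits(fit, "slb_fit"))
  method <- match.arg(method)
  if (!length(fit$free)) stop("fit has no free parameters")
  if (!is.finite(fit$chisq_total) ||
      (!is.null(fit$starts) && !any(is.finite(fit$starts$objective)))) {
    stop("fit did not converge; refusing to estimate uncertainties")
  }
  model <- fit$model
  free <- fit$free
  tab <- model$params
  lower <- stats::setNames(tab$min[tab$vary], free)
  upper <- stats::setNames(tab$max[tab$vary], free)
  best <- fit$par[free]
  if (method == "bootstrap") {
    set.seed(seed)
    cache <- .build_cache(fit$data)
    mu <- lapply(names(fit$data), function(nm) fit$curves[[nm]]$r_model)
    # standardized residuals: the data span many decades in R, so raw
    # residuals cannot be exchanged between Q points
    z <- lapply(seq_along(cache), function(i)
      (cache[[i]]$r_obs - mu[[i]]) / cache[[i]]$w)
    draws <- matrix(NA_real_, n_boot, length(free),
                    dimnames = list(NULL, free))
    for (b in seq_len(n_boot)) {
      bcache <- cache
      for (i in seq_along(bcache)) {
        idx <- sample.int(length(z[[i]]), replace = TRUE)
        bcache[[i]]$r_obs <- pmax(mu[[i]] + z[[i]][idx] * cache[[i]]$w, 0)
      }
      obj <- .make_objective(model, bcache, free)
      r <- stats::nlminb(best, obj, lower = lower, upper = upper,
                         control = list(iter.max = 200, eval.max = 600))
      draws[b, ] <- pmin(pmax(r$par, lower), upper)
    }
    alpha <- (1 - level) / 2
    out <- cbind(
      estimate = best,
      lower = apply(draws, 2, stats::quantile, alpha),
      upper = apply(draws, 2, stats::quantile, 1 - alpha)
    )
    attr(out, "samples") <- draws
    out
  } else {
    target <- fit$chisq_total + 1
    scan <- if (is.null(parm)) free else intersect(free, parm)
    out <- t(vapply(scan, function(pn) {
      .profile_bound(fit, pn, target, lower, upper)
    }, numeric(2)))
    cbind(estimate = best[scan], lower = out[, 1], upper = out[, 2])
  }
}

# scan one parameter away from the optimum (others re-optimised) until
# chi2 crosses `target`; linear interpolation of the crossing
.profile_bound <- function(fit, pn, target, lower, upper) {
  model <- fit$model
  free <- fit$free
  others <- setdiff(free, pn)
  best <- fit$par[free]
  cache <- .build_cache(fit$data)
  prof <- function(val) {
    if (!length(others)) {
      return(.make_objective(model, cache, pn)(val))
    }
    obj_full <- .make_objective(model, cache, c(others, pn))
    obj <- function(x) obj_full(c(x, val))
    stats::nlminb(best[others], obj, lower = lower[others],
                  upper = upper[others],
                  control = list(iter.max = 100, eval.max = 300))$objective
  }
  span <- (upper[[pn]] - lower[[pn]])
  bound <- function(dir) {
    x0 <- best[[pn]]; y0 <- fit$chisq_total
    for (step in span * c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16, 0.32)) {
      x1 <- min(max(best[[pn]] + dir * step, lower[[pn]]), upper[[pn]])
      y1 <- prof(x1)
      if (y1 >= target) {
        return(x0 + (x1 - x0) * (target - y0) / max(y1 - y0, 1e-12))
      }
      x0 <- x1; y0 <- y1
      if (x1 %in% c(lower[[pn]], upper[[pn]])) break
    }
    x0  # crossing beyond the bound: report the bound reached
  }
  c(bound(-1), bound(1))
}

#' @export
confint.slb_fit <- function(object, parm = NULL, level = 0.68, ...) {
  ci <- estimate_uncertainty(object, level = level, ...)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Compare two co-refined models on the same datasets
#'
#' Reports the reduced chi-square of both fits and whether the second
#' (typically richer) model is "necessary": its reduced chi-square
#' improves on the first model's by at least `factor`.
#'
#' @param fit_a,fit_b `slb_fit` objects fitted to identical datasets;
#'   by convention `fit_a` is the simpler model and `fit_b` the
#'   extension under test.
#' @param factor Improvement factor required to call the extension
#'   necessary (default 1.3).
#' @return List of class `"slb_model_comparison"`: per-model reduced
#'   chi-square, the improvement ratio `reduced(a)/reduced(b)`, the
#'   preferred model and the `necessary` flag.
#' @export
compare_models <- function(fit_a, fit_b, factor = 1.3) {
  stopifnot(inherits(fit_a, "slb_fit"), inherits(fit_b, "slb_fit"))
  same <- length(fit_a$data) == length(fit_b$data) &&
    all(mapply(function(a, b) {
      isTRUE(all.equal(a$q, b$q)) && isTRUE(all.equal(a$r, b$r))
    }, fit_a$data, fit_b$data))
  if (!same) stop("fits were not obtained on identical datasets")
  red <- c(a = fit_a$chisq_reduced, b = fit_b$chisq_reduced)
  preferred <- if (red["a"] <= red["b"]) "a" else "b"
  ratio <- red[["a"]] / red[["b"]]
  structure(
    list(reduced_chisq = red,
         delta_per_point = (fit_a$chisq_total - fit_b$chisq_total) /
           fit_a$n_points,
         preferred = preferred,
         ratio = ratio,
         necessary = ratio >= factor,
         factor = factor),
    class = "slb_model_comparison"
  )
}

#' @export
print.slb_model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model comparison> reduced chi2: a = %.4g, b = %.4g (ratio %.3g)\n",
    x$reduced_chisq["a"], x$reduced_chisq["b"], x$ratio))
  cat(sprintf("preferred: %s%s\n", x$preferred,
              if (x$necessary) sprintf(
                " (improvement >= factor %.2g: necessary)", x$factor)
              else " (improvement below necessity threshold)"))
  invisible(x)
}
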