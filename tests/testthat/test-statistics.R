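# statistics suite: descriptive table, correlation, gof, regression
# metrics, residual trend, metric ledger

test_that("descriptive reports count, moments, extremes and 10% quantiles", {
  s <- new_spectrum(0:10, rep(2, 11))
  d <- descriptive(s)
  x_row <- d[d$series == "energy", ]
  expect_identical(x_row$count, 11)
  expect_identical(x_row$mean, 5)
  expect_identical(x_row$min, 0)
  expect_identical(x_row$max, 10)
  expect_identical(x_row$q50, 5)   # linear-interpolation order statistic
  expect_identical(x_row$q10, 1)
  y_row <- d[d$series == "intensity", ]
  expect_identical(y_row$sd, 0)
  expect_error(descriptive(structure(list(x = numeric(0), y = numeric(0),
                                          x_label = "x", y_label = "y"),
                                     class = "spectrum")),
               class = "peakfitr_validation_error")
})

test_that("correlation matrix is Pearson with flagged degeneracies", {
  x <- seq(-5, 5, length.out = 101)
  g <- eval_peak("gaussian", x, list(fwhmg = 1.5))
  cm <- correlation_matrix(list(up = g, down = -g, noise = sin(7 * x)))
  expect_identical(dim(cm), c(3L, 3L))
  expect_identical(unname(diag(cm)), rep(1, 3))
  expect_lt(abs(cm["up", "down"] - (-1)), 1e-12)
  expect_identical(unname(cm), unname(t(cm)))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # identical Gaussians center-shifted by half a FWHM: strictly in (0, 1)
  g2 <- eval_peak("gaussian", x, list(center = 0.75, fwhmg = 1.5))
  r <- correlation_matrix(list(a = g, b = g2))["a", "b"]
  expect_gt(r, 0); expect_lt(r, 1)
  # zero-variance series: undefined, not silently zero
  cm0 <- correlation_matrix(list(a = g, flat = rep(1, 101)))
  expect_true(is.na(cm0["a", "flat"]))
  expect_identical(cm0["flat", "flat"], 1)
  expect_error(correlation_matrix(list(a = 1:4, b = 1:5)),
               class = "peakfitr_validation_error")
  expect_error(correlation_matrix(list(a = 1:2, b = 2:3)),
               class = "peakfitr_validation_error")
})

test_that("goodness_of_fit follows the least-squares AIC/BIC convention", {
  # N = 100, chi2 = 0.01, k = 5: aic = 100 ln(1e-4) + 10
  r <- rep(0.01, 100)  # sum r^2 = 0.01
  g <- goodness_of_fit(r, 5)
  expect_equal(g$chi2, 0.01, tolerance = 1e-15)
  expect_equal(g$aic, 100 * log(1e-4) + 10, tolerance = 1e-12)
  expect_equal(g$bic - g$aic, 5 * (log(100) - 2), tolerance = 1e-12)
  expect_equal(g$red_chi2, 0.01 / 95, tolerance = 1e-15)
  # perfect fit hits the documented floor sentinel
  g0 <- goodness_of_fit(rep(0, 50), 3)
  expect_identical(g0$chi2, 0)
  expect_equal(g0$aic, 50 * log(1e-250 / 50) + 6, tolerance = 1e-10)
  expect_error(goodness_of_fit(rep(0.1, 4), 4), class = "peakfitr_dof_error")
  expect_error(goodness_of_fit(rep(0.1, 4), -1), class = "peakfitr_validation_error")
})

test_that("regression metrics hit their exact limits", {
  y <- c(0.2, 0.5, 1.1, 0.7, 0.3)
  perfect <- regression_metrics(y, y)
  expect_identical(perfect$r2, 1)
  expect_identical(perfect$evs, 1)
  expect_identical(perfect$mae, 0)
  constant <- regression_metrics(y, rep(mean(y), 5))
  expect_equal(constant$r2, 0, tolerance = 1e-15)
  offset <- regression_metrics(y, y + 0.3)
  expect_equal(offset$evs, 1, tolerance = 1e-12)   # EVS ignores the offset
  expect_lt(offset$r2, 1)                          # R2 does not
  expect_true(is.na(regression_metrics(rep(1, 5), y)$r2))
})

test_that("evs >= r2 and both match brute force on random vectors", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n); yhat <- y + rnorm(n, sd = 0.5) + runif(1, -1, 1)
    m <- regression_metrics(y, yhat)
    r <- y - yhat
    expect_equal(m$mae, sum(abs(r)) / n, tolerance = 1e-14)
    expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-15)
    expect_equal(m$r2, 1 - sum(r^2) / sum((y - mean(y))^2), tolerance = 1e-12)
    expect_equal(m$evs, 1 - var(r) / var(y), tolerance = 1e-12)
    expect_gte(m$evs, m$r2 - 1e-12)
  }
})

test_that("residual trend is the OLS line with a confidence band", {
  x <- seq(1, 10, length.out = 50)
  zero <- residual_trend(x, rep(0, 50))
  expect_equal(zero$slope, 0, tolerance = 1e-14)
  expect_equal(zero$intercept, 0, tolerance = 1e-14)
  exact <- residual_trend(x, 2 * x + 1)
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$intercept, 1, tolerance = 1e-10)
  expect_lt(max(exact$band$upper - exact$band$lower), 1e-9)  # zero-width band
  # antisymmetric residual about mid-grid: slope from symmetry is 0
  xs <- seq(-4, 4, length.out = 81)
  anti <- residual_trend(xs, xs^3 - 16 * xs)
  expect_lt(abs(anti$intercept), 1e-12)
  expect_error(residual_trend(rep(2, 10), rnorm(10)),
               class = "peakfitr_validation_error")
})

test_that("the metric ledger records configurable metrics per fit cycle", {
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 60),
                    noise_sd = 0.02, seed = 2)
  s <- make_spectrum(tt)$spectrum
  pr <- project_from_truth(tt)
  res <- fit(pr, s)
  ledger <- NULL
  for (cycle in 1:13) ledger <- metric_history(ledger, res)
  expect_identical(nrow(ledger), 13L)
  expect_identical(ledger$cycle, 0:12)
  expect_named(ledger, c("cycle", "aic", "bic", "mse"))
  expect_equal(ledger$aic[1], res$gof$aic, tolerance = 1e-12)
  custom <- metric_history(NULL, res, c("red_chi2", "mse", "r2"))
  expect_named(custom, c("cycle", "red_chi2", "mse", "r2"))
  expect_error(metric_history(NULL, res, character(0)),
               class = "peakfitr_validation_error")
  expect_error(metric_history(NULL, res, c("aic", "mape")), "mape")
})

test_that("chi2 is non-increasing along a nested model ladder", {
  # each larger model starts from the smaller model's optimum plus one
  # zero-amplitude extra peak, so its attainable chi2 can only decrease
  truth <- six_gaussian_truth(7)
  s <- make_spectrum(truth)$spectrum
  order_amp <- order(truth$components$amplitude, decreasing = TRUE)
  extra_centers <- c(truth$components$center[order_amp[4:6]], 7.1)
  proj <- project_from_truth(ladder_truth(truth, 3))
  res <- fit(proj, s)
  chis <- res$gof$chi2
  for (step in 1:4) {
    proj <- project_with_values(proj, res$params)
    idx <- as.character(length(proj$components) + 1)
    proj$components[[length(proj$components) + 1]] <- list(
      index = idx, kind = "gaussian",
      attributes = lapply(list(
        amplitude = list(value = 0, min = 0),
        center = list(value = extra_centers[step],
                      min = extra_centers[step] - 5,
                      max = extra_centers[step] + 5),
        fwhmg = list(value = 1, min = 0.05, max = 20)),
        peakfitr:::validate_parameter_spec, path = "t"))
    res <- fit(proj, s)
    chis <- c(chis, res$gof$chi2)
  }
  expect_true(all(diff(chis) <= 1e-8))
})

test_that("fit_report prints the six tables in order", {
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 60),
                    noise_sd = 0.01, seed = 3)
  s <- make_spectrum(tt)$spectrum
  res <- fit(project_from_truth(tt), s)
  out <- capture.output(tables <- fit_report(res, s))
  headers <- c("Statistics", "Fit Statistics", "Variables and Values",
               "Correlation of Component", "Overall Linear-Correlation",
               "Regression Metrics")
  pos <- vapply(headers, function(h) grep(h, out, fixed = TRUE)[1], 0)
  expect_true(all(diff(pos) > 0))
  expect_named(tables, c("statistics", "fit_statistics", "variables",
                         "component_correlation", "overall_correlation",
                         "regression"))
  # overall correlation includes the abscissa, component matrix excludes it
  expect_true("energy" %in% colnames(tables$overall_correlation))
  expect_false("energy" %in% colnames(tables$component_correlation))
  expect_gt(tables$overall_correlation["intensity", "fit"], 0.99)
})
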