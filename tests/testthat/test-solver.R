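# model assembly, bounded least-squares fitting, uncertainties

test_that("evaluate_model composes components additively", {
  pr <- parse_input(fig4_style_json(), format = "json")
  ps <- build_names(pr$components)
  ev <- evaluate_model(ps, pr$components, 0)
  expect_equal(ev$model_curve, 2 * sqrt(log(2) / pi), tolerance = 1e-12)
  # two identical components double the curve; zero amplitude gives zero
  two <- manual_project(list(
    list(index = "1", kind = "gaussian", attributes = list(
      amplitude = list(value = 1.5), center = list(value = 2),
      fwhmg = list(value = 1))),
    list(index = "2", kind = "gaussian", attributes = list(
      amplitude = list(value = 1.5), center = list(value = 2),
      fwhmg = list(value = 1)))))
  x <- seq(-1, 5, length.out = 30)
  ev2 <- evaluate_model(build_names(two$components), two$components, x)
  expect_equal(ev2$model_curve, 2 * ev2$components$gaussian_1, tolerance = 1e-12)
  expect_equal(ev2$model_curve,
               Reduce(`+`, ev2$components), tolerance = 1e-14)
  zero <- single_gaussian_project(amplitude = 0)
  expect_identical(evaluate_model(build_names(zero$components),
                                  zero$components, x)$model_curve,
                   rep(0, length(x)))
})

test_that("a noiseless Gaussian is recovered from a 20%-perturbed start", {
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 101), noise_sd = 0, seed = 1)
  s <- make_spectrum(tt)$spectrum
  pr <- project_from_truth(tt, perturb = 0.2, seed = 3)
  res <- fit(pr, s)
  expect_true(res$success)
  v <- param_values(res$params)
  expect_rel_equal(v[["gaussian_amplitude_1"]], 2, 1e-6)
  expect_rel_equal(v[["gaussian_center_1"]], 5, 1e-6)
  expect_rel_equal(v[["gaussian_fwhmg_1"]], 1.5, 1e-6)
  expect_lt(res$gof$chi2, 1e-12)
})

test_that("data equal to the initial model leaves parameters unchanged", {
  pr <- single_gaussian_project(amplitude = 2, center = 5, fwhmg = 1.5)
  x <- seq(0, 10, length.out = 80)
  y <- evaluate_model(build_names(pr$components), pr$components, x)$model_curve
  res <- fit(pr, new_spectrum(x, y))
  expect_rel_equal(param_values(res$params), c(2, 5, 1.5), 1e-9)
  expect_lt(res$gof$chi2, 1e-20)
})

test_that("refitting from the optimum is a no-op", {
  tt <- six_gaussian_truth(4)
  s <- make_spectrum(tt)$spectrum
  res1 <- fit(project_from_truth(tt), s)
  res2 <- fit(project_with_values(project_from_truth(tt), res1$params), s)
  expect_rel_equal(param_values(res2$params), param_values(res1$params), 1e-8)
  expect_lte(res2$gof$chi2, res1$gof$chi2 * (1 + 1e-12))
})

test_that("residual invariants and covariance structure hold", {
  tt <- six_gaussian_truth(2)
  s <- make_spectrum(tt)$spectrum
  res <- fit(project_from_truth(tt), s)
  expect_length(res$residual, length(s$x))
  expect_lt(max(abs(res$model_curve - Reduce(`+`, res$components))), 1e-10)
  expect_equal(res$residual, s$y - res$model_curve, tolerance = 1e-14)
  # covariance: symmetric positive semi-definite, stderr = sqrt(diag)
  cv <- res$covariance
  expect_identical(cv, t(cv))
  expect_gte(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  free <- free_parameters(res$params)
  expect_equal(res$params$stderr[match(free, res$params$name)],
               unname(sqrt(diag(cv))), tolerance = 1e-12)
  # residual sum of squares did not increase relative to the start
  init <- evaluate_model(resolve_expressions(build_names(project_from_truth(tt)$components)),
                         project_from_truth(tt)$components, s$x)$model_curve
  expect_lte(res$gof$chi2, sum((s$y - init)^2))
})

test_that("the fit is invariant to an abscissa shift", {
  tt <- truth_table(data.frame(kind = "gaussian",
                               amplitude = c(1, 0.7), center = c(4, 6.5),
                               width = c(1.2, 1)),
                    grid = seq(0, 10, length.out = 120),
                    noise_sd = 0.01, seed = 9)
  s <- make_spectrum(tt)$spectrum
  res0 <- fit(project_from_truth(tt), s)
  delta <- 100
  tt_sh <- tt
  tt_sh$components$center <- tt$components$center + delta
  res1 <- fit(project_from_truth(tt_sh), preprocess(s, shift = delta))
  v0 <- param_values(res0$params); v1 <- param_values(res1$params)
  i_c <- grep("center", names(v0))
  expect_rel_equal(v1[i_c], v0[i_c] + delta, 1e-6)
  expect_rel_equal(v1[-i_c], v0[-i_c], 1e-6)
})

test_that("method names are forwarded and unknown ones rejected", {
  pr <- single_gaussian_project(amplitude = 1.8, center = 4.8, fwhmg = 1.4)
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 90), noise_sd = 0, seed = 1)
  s <- make_spectrum(tt)$spectrum
  res_lm <- fit(pr, s, method = "leastsq")
  res_port <- fit(pr, s, method = "nlminb")
  expect_rel_equal(param_values(res_lm$params), c(2, 5, 1.5), 1e-6)
  expect_rel_equal(param_values(res_port$params), c(2, 5, 1.5), 1e-4)
  # covariance only for the least-squares family
  expect_false(is.null(res_lm$covariance))
  expect_null(res_port$covariance)
  expect_true(all(is.na(res_port$params$stderr)))
  expect_error(fit(pr, s, method = "annealing"), class = "peakfitr_model_error")
  # method kwargs reach the optimizer: a crippled iteration budget; the
  # resulting non-convergence is reported as data, not raised
  expect_warning(res_tight <- fit(pr, s, method = "leastsq", maxiter = 1),
                 "maxiter")
  expect_false(res_tight$success)
  expect_s3_class(res_tight, "fit_result")
  expect_gt(res_tight$gof$chi2, res_lm$gof$chi2)
})

test_that("under-determined problems raise a degrees-of-freedom error", {
  pr <- single_gaussian_project()
  s <- new_spectrum(c(0, 1, 2), c(0.1, 0.9, 0.1))
  expect_error(fit(pr, s), class = "peakfitr_dof_error")
})

test_that("1-sigma profile interval matches the linear-regression stderr", {
  set.seed(42)
  x <- seq(0.5, 10, length.out = 60)
  y <- 2 * x + rnorm(60, 0, 0.3)
  pr <- manual_project(list(list(index = "1", kind = "linear", attributes = list(
    intercept = list(value = 0, vary = FALSE), slope = list(value = 1.5)))))
  res <- fit(pr, new_spectrum(x, y))
  ci <- confidence_intervals(res, sigmas = c(1, 2, 3))
  i <- res$params$name == "linear_slope_1"
  best <- res$params$value[i]; se <- res$params$stderr[i]
  one <- ci[ci$sigma == 1, ]
  expect_lt(abs((best - one$lower) / se - 1), 0.15)
  expect_lt(abs((one$upper - best) / se - 1), 0.15)
  # nesting and symmetry
  for (sg in c(2, 3)) {
    outer <- ci[ci$sigma == sg, ]
    expect_lt(outer$lower, one$lower)
    expect_gt(outer$upper, one$upper)
  }
  expect_true(all(ci$lower < best & best < ci$upper))
  asym <- abs((one$upper - best) - (best - one$lower)) /
    ((one$upper - one$lower) / 2)
  expect_lt(asym, 0.1)
})

test_that("a parameter at a bound yields a one-sided non-converged interval", {
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 90),
                    noise_sd = 0.01, seed = 5)
  s <- make_spectrum(tt)$spectrum
  pr <- single_gaussian_project(amplitude = 1.7, center = 5, fwhmg = 1.5,
                                amp_max = 1.8)
  res <- fit(pr, s)
  i <- res$params$name == "gaussian_amplitude_1"
  expect_equal(res$params$value[i], 1.8, tolerance = 1e-8)  # pegged
  ci <- confidence_intervals(res, sigmas = 1)
  row <- ci[ci$name == "gaussian_amplitude_1", ]
  expect_true(is.na(row$upper))
  expect_false(is.na(row$lower))
})
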