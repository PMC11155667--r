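# Fit-statistics suite: descriptive table, chi-square/AIC/BIC block,
# Pearson correlation matrices, regression metrics, residual-trend
# regression and the fit-cycle metric ledger.

CHI2_FLOOR <- 1e-250

#' Descriptive statistics of a spectrum
#'
#' Count, mean, standard deviation, minimum, maximum and quantiles at 10%
#' increments for both the abscissa and intensity columns. Quantiles use
#' linear interpolation between order statistics.
#'
#' @param s a `spectrum`.
#' @return data.frame with one row per series.
#' @export
descriptive <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (!length(s$x)) stop_invalid("empty spectrum")
  one <- function(v) {
    q <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
    c(count = length(v), mean = mean(v), sd = stats::sd(v),
      min = min(v), stats::setNames(q, paste0("q", seq(10, 90, 10))), max = max(v))
  }
  out <- rbind(one(s$x), one(s$y))
  data.frame(series = c(s$x_label, s$y_label), out,
             check.names = FALSE, row.names = NULL)
}

#' Pearson correlation matrix of labeled series
#'
#' @param series named list of equal-length numeric vectors (length >= 3).
#'   Pairs involving a zero-variance series are reported as `NA`
#'   (undefined), never silently zero.
#' @return symmetric matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
correlation_matrix <- function(series) {
  if (!is.list(series) || is.null(names(series)) || !length(series)) {
    stop_invalid("series must be a named list")
  }
  len <- lengths(series)
  if (length(unique(len)) != 1L) stop_invalid("series lengths differ")
  if (len[1] < 3L) stop_invalid("series must have length >= 3")
  m <- do.call(cbind, series)
  sds <- apply(m, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(m))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  structure(cm, class = c("correlation_matrix", class(cm)))
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Goodness-of-fit block
#'
#' Unweighted residual statistics in the least-squares likelihood
#' convention: `chi2 = sum(r^2)`, `aic = N log(chi2/N) + 2k`,
#' `bic = N log(chi2/N) + k log N`, so `bic - aic = k (log N - 2)`
#' identically. `chi2` is floored at `1e-250` before the logarithm so a
#' perfect fit yields a documented finite sentinel.
#'
#' @param residual numeric residual vector (data minus model).
#' @param k number of free parameters (`0 <= k < N`).
#' @return list with `chi2`, `red_chi2`, `aic`, `bic`, `N`, `k`.
#' @export
goodness_of_fit <- function(residual, k) {
  n <- length(residual)
  k <- as.integer(k)
  if (k < 0) stop_invalid("k must be >= 0")
  if (n <= k) {
    stop(errorCondition(
      sprintf("degrees of freedom <= 0: N = %d points, k = %d free parameters", n, k),
      class = c("peakfitr_dof_error", "error")))
  }
  chi2 <- sum(residual^2)
  chi2_log <- max(chi2, CHI2_FLOOR)
  list(chi2 = chi2,
       red_chi2 = chi2 / (n - k),
       aic = n * log(chi2_log / n) + 2 * k,
       bic = n * log(chi2_log / n) + k * log(n),
       N = n, k = k)
}

#' Regression metrics of a fit
#'
#' Mean absolute error, mean squared error, its square root, the
#' coefficient of determination R^2 and the explained variance score
#' (EVS). R^2 penalizes a constant prediction offset; EVS does not, so
#' `evs >= r2` always.
#'
#' @param y observed vector.
#' @param yhat predicted vector of the same length (>= 2).
#' @return list with `mae`, `mse`, `rmse`, `r2`, `evs` (`r2`/`evs` are
#'   `NA` when `var(y) == 0`).
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_invalid("y and yhat lengths differ")
  if (length(y) < 2L) stop_invalid("need at least 2 points")
  r <- y - yhat
  mse <- mean(r^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- NA_real_; evs <- NA_real_
  } else {
    r2 <- 1 - sum(r^2) / sst
    evs <- 1 - stats::var(r) / stats::var(y)
  }
  list(mae = mean(abs(r)), mse = mse, rmse = sqrt(mse), r2 = r2, evs = evs)
}

#' Linear trend of the residual with a confidence band
#'
#' Ordinary least-squares line through `(x, residual)` with a pointwise
#' t-distribution confidence band; a flat, centered line indicates an
#' unbiased fit.
#'
#' @param x abscissa vector (non-constant, length >= 3).
#' @param residual residual vector.
#' @param conf band probability level (default 0.95).
#' @return list with `slope`, `intercept` and a `band` data.frame
#'   (`x`, `fit`, `lower`, `upper`).
#' @export
residual_trend <- function(x, residual, conf = 0.95) {
  if (length(x) < 3L) stop_invalid("need at least 3 points")
  if (stats::sd(x) == 0) stop_invalid("constant abscissa")
  fit <- stats::lm(residual ~ x, data = data.frame(x = x, residual = residual))
  pred <- suppressWarnings(
    stats::predict(fit, interval = "confidence", level = conf))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       band = data.frame(x = x, fit = pred[, "fit"],
                         lower = pred[, "lwr"], upper = pred[, "upr"]))
}

VALID_METRICS <- c("aic", "bic", "chi2", "red_chi2",
                   "mae", "mse", "rmse", "r2", "evs")

#' Append a fit to the metric history ledger
#'
#' Tracks configurable metrics from fit cycle to fit cycle (default AIC,
#' BIC, MSE) so successive model refinements can be compared.
#'
#' @param ledger an existing `metric_ledger` or `NULL` to start one.
#' @param result a `fit_result`.
#' @param metrics character vector of metric names drawn from
#'   `r paste(VALID_METRICS, collapse = ", ")`; must be nonempty and match
#'   the ledger's existing metric list.
#' @return a `metric_ledger` data.frame with a `cycle` column plus one
#'   column per metric.
#' @export
metric_history <- function(ledger, result, metrics = c("aic", "bic", "mse")) {
  if (!length(metrics)) stop_invalid("metric list must be nonempty")
  bad <- setdiff(metrics, VALID_METRICS)
  if (length(bad)) {
    stop_invalid("unknown metric(s) %s; valid: %s",
                 paste(bad, collapse = ", "), paste(VALID_METRICS, collapse = ", "))
  }
  stopifnot(inherits(result, "fit_result"))
  y <- result$model_curve + result$residual
  reg <- regression_metrics(y, result$model_curve)
  pool <- c(result$gof, reg)
  row <- as.data.frame(pool[metrics])
  row <- cbind(cycle = if (is.null(ledger)) 0L else nrow(ledger), row)
  if (!is.null(ledger)) {
    if (!identical(names(ledger), names(row))) {
      stop_invalid("metric list differs from the ledger's existing columns")
    }
    row <- rbind(ledger, row)
  }
  structure(row, class = c("metric_ledger", "data.frame"))
}

#' Print the six-table statistics report of a fit
#'
#' Reproduces the standard console report: descriptive statistics of the
#' input, the fit-statistics block, the variables-and-values table, the
#' component correlation matrix, the overall linear correlation (including
#' the abscissa) and the regression metrics.
#'
#' @param result a `fit_result`.
#' @param s the fitted `spectrum`.
#' @return the assembled tables, invisibly (a named list).
#' @export
fit_report <- function(result, s) {
  stopifnot(inherits(result, "fit_result"), inherits(s, "spectrum"))
  tables <- report_tables(result, s)
  hr <- function(t) cat("\n== ", t, " ==\n", sep = "")
  hr("Statistics")
  print(tables$statistics, row.names = FALSE, digits = 6)
  hr("Fit Statistics")
  print(tables$fit_statistics, row.names = FALSE, digits = 6)
  hr("Variables and Values")
  print(tables$variables, row.names = FALSE, digits = 6)
  hr("Correlation of Component")
  print(tables$component_correlation)
  hr("Overall Linear-Correlation")
  print(tables$overall_correlation)
  hr("Regression Metrics")
  print(tables$regression, row.names = FALSE, digits = 6)
  invisible(tables)
}

report_tables <- function(result, s) {
  ps <- result$params
  gof <- result$gof
  reg <- regression_metrics(s$y, result$model_curve)
  series <- c(list(energy = s$x, intensity = s$y,
                   fit = result$model_curve, residual = result$residual),
              result$components)
  overall <- correlation_matrix(series)
  comp <- correlation_matrix(series[names(series) != "energy"])
  list(
    statistics = descriptive(s),
    fit_statistics = data.frame(chi2 = gof$chi2, red_chi2 = gof$red_chi2,
                                aic = gof$aic, bic = gof$bic,
                                N = gof$N, k = gof$k),
    variables = data.frame(name = ps$name, value = ps$value,
                           stderr = ps$stderr,
                           rel_err = abs(ps$stderr / ps$value),
                           vary = ps$vary,
                           expr = ifelse(is.na(ps$expr), "", ps$expr)),
    component_correlation = comp,
    overall_correlation = overall,
    regression = as.data.frame(reg))
}
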