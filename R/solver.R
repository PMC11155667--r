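# Composite-model assembly and bounded least-squares fitting.
# The default engine is bounded Levenberg-Marquardt (minpack.lm::nls.lm);
# "nlminb" selects the PORT quasi-Newton minimizer on the residual sum of
# squares. Covariance-based standard errors are attempted for the
# least/least_squares family only; other methods report no stderr.

LM_METHODS <- c("least_squares", "least", "leastsq")

component_label <- function(co) sprintf("%s_%s", co$kind, co$index)

component_attrs <- function(ps_values, co, suffix = "") {
  nm <- sprintf("%s_%s_%s%s", co$kind, names(co$attributes), co$index, suffix)
  stats::setNames(as.list(ps_values[nm]), names(co$attributes))
}

#' Evaluate the composite model and its per-component curves
#'
#' @param ps a resolved `parameter_set` (see [resolve_expressions()]).
#' @param components component list of a `fit_project`.
#' @param grid abscissa vector.
#' @param suffix internal per-spectrum parameter-name suffix used by the
#'   simultaneous-fitting expansion ("" for a single spectrum).
#' @return list with `model_curve` and `components` (named list of
#'   curves); the model curve is their elementwise sum.
#' @export
evaluate_model <- function(ps, components, grid, suffix = "") {
  vals <- param_values(ps)
  curves <- lapply(components, function(co) {
    eval_component(co$kind, grid, component_attrs(vals, co, suffix))
  })
  names(curves) <- vapply(components, component_label, "")
  model <- Reduce(`+`, curves, accumulate = FALSE)
  list(model_curve = model, components = curves)
}

fit_method <- function(project, method = NULL) {
  m <- method %||% project$settings$method %||% "least_squares"
  tolower(m)
}

run_optimizer <- function(residual_fn, start, lower, upper, method, kwargs) {
  n_eval <- 0L
  counting <- function(p) { n_eval <<- n_eval + 1L; residual_fn(p) }
  if (method %in% LM_METHODS) {
    ctrl_args <- kwargs[names(kwargs) %in% names(formals(minpack.lm::nls.lm.control))]
    ctrl <- do.call(minpack.lm::nls.lm.control,
                    utils::modifyList(list(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-12), ctrl_args))
    out <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = counting, control = ctrl),
      error = function(e) e)
    if (inherits(out, "error")) {
      return(list(par = start, success = FALSE,
                  message = conditionMessage(out), n_eval = n_eval))
    }
    list(par = stats::setNames(as.numeric(out$par), names(start)),
         success = out$info %in% 1:4,
         message = out$message, n_eval = n_eval)
  } else if (method %in% c("nlminb", "port")) {
    obj <- function(p) sum(counting(p)^2)
    out <- tryCatch(
      stats::nlminb(start, obj, lower = lower, upper = upper,
                    control = kwargs[names(kwargs) %in%
                                     c("eval.max", "iter.max", "rel.tol", "abs.tol")]),
      error = function(e) e)
    if (inherits(out, "error")) {
      return(list(par = start, success = FALSE,
                  message = conditionMessage(out), n_eval = n_eval))
    }
    list(par = stats::setNames(as.numeric(out$par), names(start)),
         success = out$convergence == 0, message = out$message, n_eval = n_eval)
  } else {
    stop_model("unknown optimizer method '%s'; supported: %s, nlminb", method,
               paste(LM_METHODS, collapse = ", "))
  }
}

# numerical Jacobian of the residual with respect to the free parameters,
# central differences, one-sided at an active bound
residual_jacobian <- function(residual_fn, par, lower, upper) {
  r0 <- residual_fn(par)
  J <- matrix(0, length(r0), length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- max(1e-8, abs(par[j]) * 1e-7)
    up <- pmin(par[j] + h, upper[j]); dn <- pmax(par[j] - h, lower[j])
    if (up == dn) next
    pu <- par; pu[j] <- up
    pd <- par; pd[j] <- dn
    J[, j] <- (residual_fn(pu) - residual_fn(pd)) / (up - dn)
  }
  J
}

covariance_from_jacobian <- function(J, chi2, dof) {
  jtj <- crossprod(J)
  inv <- tryCatch(chol2inv(chol(jtj)), error = function(e) NULL)
  if (is.null(inv)) {
    inv <- tryCatch(solve(jtj), error = function(e) NULL)
  }
  if (is.null(inv)) return(NULL)
  s2 <- if (dof > 0) chi2 / dof else 0
  cov <- s2 * inv
  dimnames(cov) <- list(colnames(J), colnames(J))
  (cov + t(cov)) / 2
}

#' Fit a declarative model to a spectrum
#'
#' Assembles the composite model from the project's components, minimizes
#' the unweighted residual sum of squares under the parameter bounds, and
#' fills in standard errors from the covariance of the free parameters
#' (for the least/least_squares method family). Optimizer non-convergence
#' is reported via `success = FALSE`, not as an error, so statistics can
#' still be printed.
#'
#' @param project a `fit_project` from [parse_input()].
#' @param spectrum a `spectrum`.
#' @param method optional optimizer override (default: the project's
#'   `settings$method`, falling back to `"least_squares"`).
#' @param ... optimizer keyword arguments, merged over the project's
#'   `settings$method_kwargs` and forwarded unmodified.
#' @return a `fit_result`: `params` (with `stderr`), `model_curve`,
#'   `components`, `residual`, `covariance`, `gof`, `success`, `n_eval`.
#' @export
fit <- function(project, spectrum, method = NULL, ...) {
  stopifnot(inherits(project, "fit_project"), inherits(spectrum, "spectrum"))
  ps <- resolve_expressions(build_names(project$components))
  fit_parameter_set(ps, project$components, spectrum$x, spectrum$y,
                    method = fit_method(project, method),
                    kwargs = utils::modifyList(
                      as.list(project$settings$method_kwargs %||% list()),
                      list(...)))
}

# core fitting routine shared by fit() and fit_simultaneous(); model_fn
# maps a resolved parameter_set to list(model_curve, components)
fit_parameter_set <- function(ps, components, x, y, method, kwargs = list(),
                              model_fn = NULL) {
  if (is.null(model_fn)) {
    model_fn <- function(p) evaluate_model(p, components, x)
  }
  free <- free_parameters(ps)
  if (!length(free)) stop_invalid("model has no free parameters")
  if (length(y) <= length(free)) {
    stop(errorCondition(
      sprintf("under-determined fit: %d points <= %d free parameters",
              length(y), length(free)),
      class = c("peakfitr_dof_error", "error")))
  }
  i_free <- match(free, ps$name)
  start <- stats::setNames(ps$value[i_free], free)
  lower <- ps$min[i_free]; upper <- ps$max[i_free]
  residual_fn <- function(p) {
    y - model_fn(set_free_values(ps, stats::setNames(p, free)))$model_curve
  }
  opt <- run_optimizer(residual_fn, start, lower, upper, method, kwargs)
  ps_fit <- set_free_values(ps, opt$par)
  ev <- model_fn(ps_fit)
  residual <- y - ev$model_curve
  gof <- goodness_of_fit(residual, length(free))
  covariance <- NULL
  if (method %in% LM_METHODS && opt$success) {
    J <- residual_jacobian(residual_fn, opt$par, lower, upper)
    covariance <- covariance_from_jacobian(J, gof$chi2, gof$N - gof$k)
    if (!is.null(covariance)) {
      ps_fit$stderr[match(free, ps_fit$name)] <- sqrt(pmax(diag(covariance), 0))
    }
  }
  structure(list(params = ps_fit, model_curve = ev$model_curve,
                 components = ev$components, residual = residual,
                 covariance = covariance, gof = gof,
                 success = opt$success, message = opt$message,
                 n_eval = opt$n_eval,
                 .ctx = list(components = components, x = x, y = y,
                             method = method, kwargs = kwargs,
                             model_fn = model_fn)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s, chi2 = %.6g, red_chi2 = %.6g, %d free parameters, %d evaluations>\n",
              if (x$success) "converged" else "NOT converged",
              x$gof$chi2, x$gof$red_chi2, x$gof$k, x$n_eval))
  invisible(x)
}

sigma_to_prob <- function(sigma) stats::pnorm(sigma) - stats::pnorm(-sigma)

# chi-square of the model with one free parameter fixed at `value`,
# all remaining free parameters refit
profile_chi2 <- function(ctx, ps_best, pname, value) {
  ps <- ps_best
  i <- match(pname, ps$name)
  ps$value[i] <- value
  ps$vary[i] <- FALSE
  free <- free_parameters(ps)
  if (!length(free)) {
    ev <- ctx$model_fn(resolve_expressions(ps))
    return(sum((ctx$y - ev$model_curve)^2))
  }
  res <- fit_parameter_set(ps, ctx$components, ctx$x, ctx$y,
                           method = ctx$method, kwargs = ctx$kwargs,
                           model_fn = ctx$model_fn)
  res$gof$chi2
}

#' Profile (F-test) confidence intervals of the free parameters
#'
#' For each free parameter the others are refit while the target is
#' stepped away from its best value; the probability that the chi-square
#' increase is explained by chance is assessed with an F statistic, and
#' the interval bound at each sigma level is located by root finding.
#' Intended for unconstrained, converged fits; a side that cannot be
#' bracketed (e.g. the parameter sits on a bound) is reported `NA`.
#'
#' @param result a converged `fit_result`.
#' @param sigmas probability levels expressed in Gaussian sigmas
#'   (default 1, 2, 3 -> 68.27%, 95.45%, 99.73%).
#' @param max_steps maximum number of stderr-sized steps when bracketing.
#' @return data.frame with columns `name`, `sigma`, `prob`, `lower`,
#'   `upper`; intervals at increasing sigma are nested.
#' @export
confidence_intervals <- function(result, sigmas = c(1, 2, 3), max_steps = 200) {
  stopifnot(inherits(result, "fit_result"))
  if (!result$success) stop_invalid("confidence intervals require a converged fit")
  ctx <- result$.ctx
  ps_best <- result$params
  free <- free_parameters(ps_best)
  if (!length(free)) stop_invalid("model has no free parameters")
  chi2_0 <- result$gof$chi2
  N <- result$gof$N; k <- result$gof$k
  probs <- sigma_to_prob(sigmas)
  prob_at <- function(pname, value) {
    chi2_f <- profile_chi2(ctx, ps_best, pname, value)
    f <- max(chi2_f / chi2_0 - 1, 0) * (N - k)
    stats::pf(f, 1, N - k)
  }
  rows <- list()
  for (pname in free) {
    i <- match(pname, ps_best$name)
    best <- ps_best$value[i]
    se <- ps_best$stderr[i]
    if (!is.finite(se) || se <= 0) se <- max(abs(best) * 0.1, 1e-4)
    bounds <- c(ps_best$min[i], ps_best$max[i])
    side_limit <- function(direction, prob_target) {
      step <- 1
      v_prev <- best
      while (step <= max_steps) {
        v <- best + direction * step * se
        v <- if (direction < 0) max(v, bounds[1]) else min(v, bounds[2])
        p <- prob_at(pname, v)
        if (p >= prob_target) {
          return(stats::uniroot(function(z) prob_at(pname, z) - prob_target,
                                lower = min(v_prev, v), upper = max(v_prev, v),
                                tol = se * 1e-4)$root)
        }
        if (v == bounds[1] || v == bounds[2]) return(NA_real_)  # bound hit
        v_prev <- v
        step <- step * 2
      }
      NA_real_
    }
    for (s in seq_along(sigmas)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = pname, sigma = sigmas[s], prob = probs[s],
        lower = side_limit(-1, probs[s]), upper = side_limit(+1, probs[s]))
    }
  }
  do.call(rbind, rows)
}
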