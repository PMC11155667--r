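# Simultaneous (global) fitting: several spectra share one component list;
# parameters are duplicated per spectrum with a "_s<j>" suffix and the peak
# energies of every spectrum beyond the first are frozen onto the first
# spectrum's centers through autogenerated constraint expressions.

spectrum_suffix <- function(j) sprintf("_s%d", j)

is_center_attr <- function(attr) attr == "center"
is_width_attr <- function(attr) attr %in% c("fwhmg", "fwhml", "fwhmv", "gamma", "sigma")

#' Expand a component model over several spectra
#'
#' Each base parameter is duplicated once per spectrum with a `_s<j>`
#' suffix. For every spectrum beyond the first, each `center` parameter
#' receives the autogenerated expression tying it to the first spectrum's
#' center, so peak energies are shared while amplitudes (and, by default,
#' widths) remain free per spectrum. With `n_spectra = 1` the plain
#' single-spectrum names are returned unchanged.
#'
#' @param components component list of a `fit_project`.
#' @param n_spectra number of spectra (>= 1).
#' @param tie_widths also freeze width parameters (`fwhm*`, `gamma`,
#'   `sigma`) across spectra (default `FALSE`).
#' @return a `parameter_set` over the expanded names.
#' @export
expand_model <- function(components, n_spectra, tie_widths = FALSE) {
  if (!is.numeric(n_spectra) || n_spectra < 1) {
    stop_invalid("n_spectra must be >= 1")
  }
  n_spectra <- as.integer(n_spectra)
  base <- build_names(components)
  if (n_spectra == 1L) return(base)
  # attribute name aligned with each registry row (kinds may contain
  # underscores, so the name itself is not parsed)
  attr_names <- unlist(lapply(components, function(co) names(co$attributes)),
                       use.names = FALSE)
  attr_of <- function(name) attr_names[match(name, base$name)]
  blocks <- lapply(seq_len(n_spectra), function(j) {
    b <- base
    b$name <- paste0(b$name, spectrum_suffix(j))
    if (j > 1L) {
      for (i in seq_len(nrow(b))) {
        a <- attr_of(base$name[i])
        tie <- is_center_attr(a) || (tie_widths && is_width_attr(a))
        if (tie && is.na(b$expr[i])) {
          b$expr[i] <- paste0(base$name[i], spectrum_suffix(1L))
          b$vary[i] <- FALSE
        } else if (!is.na(b$expr[i])) {
          # user expressions reference same-spectrum parameters
          for (nm in base$name) {
            b$expr[i] <- gsub(paste0("\\b", nm, "\\b"),
                              paste0(nm, spectrum_suffix(j)), b$expr[i])
          }
        }
      }
    } else if (any(!is.na(b$expr))) {
      for (i in which(!is.na(b$expr))) {
        for (nm in base$name) {
          b$expr[i] <- gsub(paste0("\\b", nm, "\\b"),
                            paste0(nm, spectrum_suffix(1L)), b$expr[i])
        }
      }
    }
    b
  })
  all <- do.call(rbind, blocks)
  parameter_set(all$name, all$value, all$min, all$max, all$vary, all$expr)
}

#' Stack several spectra into one combined structure
#'
#' Spectra are concatenated in input order; per-spectrum slice boundaries
#' are kept so [unstack()] reproduces the inputs exactly.
#'
#' @param spectra nonempty list of `spectrum` objects.
#' @return a `stacked_data` list with `x`, `y`, `spectrum_id` and a
#'   `slices` data.frame (`start`, `end`, 1-based inclusive).
#' @export
stack_spectra <- function(spectra) {
  if (!is.list(spectra) || !length(spectra)) stop_invalid("need at least one spectrum")
  lapply(spectra, function(s) stopifnot(inherits(s, "spectrum")))
  lens <- vapply(spectra, function(s) length(s$x), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(
    x = unlist(lapply(spectra, `[[`, "x"), use.names = FALSE),
    y = unlist(lapply(spectra, `[[`, "y"), use.names = FALSE),
    spectrum_id = rep(seq_along(spectra), lens),
    slices = data.frame(start = starts, end = ends),
    labels = lapply(spectra, function(s) list(x = s$x_label, y = s$y_label))),
    class = "stacked_data")
}

#' Unstack combined data back into the original spectra
#'
#' @param stacked a `stacked_data` object from [stack_spectra()].
#' @return list of `spectrum` objects identical to the stacked inputs.
#' @export
unstack <- function(stacked) {
  stopifnot(inherits(stacked, "stacked_data"))
  lapply(seq_len(nrow(stacked$slices)), function(j) {
    i <- stacked$slices$start[j]:stacked$slices$end[j]
    new_spectrum(stacked$x[i], stacked$y[i],
                 x_label = stacked$labels[[j]]$x,
                 y_label = stacked$labels[[j]]$y)
  })
}

#' Fit one model to several spectra simultaneously
#'
#' The expanded model (see [expand_model()]) is fit against the stacked
#' data; the joint residual is the concatenation of the per-spectrum
#' residuals and the joint AIC/BIC/chi-square uses the free-parameter
#' count of the expanded model. Regression metrics are computed for each
#' spectrum against its own slice of the joint fit.
#'
#' @param project a `fit_project`; its component list applies to every
#'   spectrum.
#' @param spectra list of `spectrum` objects.
#' @param tie_widths passed to [expand_model()].
#' @param method optional optimizer override.
#' @param ... optimizer keyword arguments.
#' @return list with `joint` (a `fit_result` over the stacked data),
#'   `per_spectrum` (one `fit_result`-like record per spectrum with its
#'   slice curves, residual and `regression` metrics) and `gof` (the
#'   joint goodness of fit).
#' @export
fit_simultaneous <- function(project, spectra, tie_widths = FALSE,
                             method = NULL, ...) {
  stopifnot(inherits(project, "fit_project"))
  stacked <- stack_spectra(spectra)
  n <- length(spectra)
  ps <- resolve_expressions(expand_model(project$components, n, tie_widths))
  suffixes <- if (n == 1L) "" else vapply(seq_len(n), spectrum_suffix, "")
  model_fn <- function(p) {
    per <- lapply(seq_len(n), function(j) {
      evaluate_model(p, project$components, spectra[[j]]$x, suffix = suffixes[j])
    })
    list(model_curve = unlist(lapply(per, `[[`, "model_curve"), use.names = FALSE),
         components = stats::setNames(per, paste0("spectrum_", seq_len(n))))
  }
  joint <- fit_parameter_set(ps, project$components, stacked$x, stacked$y,
                             method = fit_method(project, method),
                             kwargs = utils::modifyList(
                               as.list(project$settings$method_kwargs %||% list()),
                               list(...)),
                             model_fn = model_fn)
  per_spectrum <- lapply(seq_len(n), function(j) {
    i <- stacked$slices$start[j]:stacked$slices$end[j]
    ev <- joint$components[[paste0("spectrum_", j)]]
    residual <- spectra[[j]]$y - ev$model_curve
    structure(list(params = slice_parameters(joint$params, suffixes[j]),
                   model_curve = ev$model_curve,
                   components = ev$components,
                   residual = residual,
                   covariance = NULL,
                   gof = joint$gof,
                   regression = regression_metrics(spectra[[j]]$y, ev$model_curve),
                   success = joint$success,
                   n_eval = joint$n_eval,
                   .ctx = NULL),
              class = "fit_result")
  })
  list(joint = joint, per_spectrum = per_spectrum, gof = joint$gof)
}

# restrict an expanded parameter_set to one spectrum's block, restoring
# the base single-spectrum names
slice_parameters <- function(ps, suffix) {
  if (!nzchar(suffix)) return(ps)
  keep <- endsWith(ps$name, suffix)
  out <- ps[keep, , drop = FALSE]
  out$name <- substr(out$name, 1, nchar(out$name) - nchar(suffix))
  class(out) <- c("parameter_set", "data.frame")
  out
}
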