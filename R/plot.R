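# Static fit figure: data, composite fit and components on top, residual
# with its linear trend and confidence band below.

#' Plot a fit result
#'
#' Two-panel figure: the spectrum with the composite fit and the
#' individual component curves, and the residual with its least-squares
#' trend line and 95% confidence band.
#'
#' @param result a `fit_result`.
#' @param s the fitted `spectrum`.
#' @param conf confidence level of the residual-trend band.
#' @return a ggplot object (patchable via `ggplot2` facets).
#' @export
plot_fit <- function(result, s, conf = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("plot_fit requires the ggplot2 package")
  }
  stopifnot(inherits(result, "fit_result"), inherits(s, "spectrum"))
  comp <- do.call(rbind, lapply(names(result$components), function(nm) {
    data.frame(x = s$x, y = result$components[[nm]], series = nm)
  }))
  top <- data.frame(x = s$x, data = s$y, fit = result$model_curve)
  trend <- residual_trend(s$x, result$residual, conf = conf)
  resid_df <- cbind(data.frame(residual = result$residual), trend$band)
  main <- rbind(
    data.frame(x = top$x, y = top$data, series = "data", panel = "spectrum"),
    data.frame(x = top$x, y = top$fit, series = "fit", panel = "spectrum"),
    data.frame(x = comp$x, y = comp$y, series = comp$series, panel = "spectrum"),
    data.frame(x = resid_df$x, y = resid_df$residual, series = "residual",
               panel = "residual"))
  main$panel <- factor(main$panel, levels = c("spectrum", "residual"))
  ggplot2::ggplot(main, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$series)) +
    ggplot2::geom_line(data = main[main$panel == "spectrum", ]) +
    ggplot2::geom_point(data = main[main$panel == "residual", ], size = 0.6) +
    ggplot2::geom_ribbon(data = cbind(resid_df, panel = factor("residual",
                           levels = c("spectrum", "residual"))),
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = cbind(resid_df, panel = factor("residual",
                         levels = c("spectrum", "residual"))),
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, color = "red") +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::labs(x = s$x_label, y = s$y_label, color = NULL) +
    ggplot2::theme_minimal()
}
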