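#' Plot classification performance summaries
#'
#' Dot-and-interval display of the summarised accuracy measures: one panel per
#' measure, methods on the x axis, points at the replicate mean with the 90th
#' percentile interval. When `x` names a design column (e.g. `"K"` for a
#' provider-count sweep) the panel x axis sweeps that parameter and methods
#' are distinguished by colour.
#'
#' @param summary A [summarize_performance()] result.
#' @param measures Measures to show (default: all but eagerness has no
#'   interval and is shown as points only).
#' @param x Optional design column to place on the x axis.
#' @return A ggplot object.
#' @export
plot_performance <- function(summary,
                             measures = c("sensitivity", "specificity",
                                          "ppv", "npv", "eagerness"),
                             x = NULL) {
  df <- dplyr::filter(summary, .data$measure %in% measures)
  if (is.null(x)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo90,
                                            ymax = .data$hi90),
                               na.rm = TRUE)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$mean,
                                          colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point()
  }
  p +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "mean over replicates (90th percentile interval)",
                  x = x %||% "method") +
    ggplot2::theme_bw()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.performance_summary <- function(object, ...) {
  plot_performance(object, ...)
}
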