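#' Plot an orientation histogram
#'
#' Bin weights over orientation, with the groove axis at 0 degrees.
#'
#' @param hist an [orientation_histogram()].
#' @return A ggplot.
#' @export
plot_orientation_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$angle, y = .data$weight)) +
    ggplot2::geom_col(width = diff(hist$angle[1:2]), fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "orientation from groove axis (deg)",
                  y = "normalized spectral weight") +
    ggplot2::theme_minimal()
}

#' @rdname plot_orientation_histogram
#' @param object,... autoplot arguments.
#' @method autoplot orientation_histogram
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  plot_orientation_histogram(object)
}

#' Plot a depth or signal profile with groove intervals
#'
#' @param profile tibble with `x` and `z` (depth) or `value` (signal).
#' @param grooves optional groove interval tibble to shade.
#' @return A ggplot.
#' @export
plot_profile <- function(profile, grooves = NULL) {
  ycol <- if ("z" %in% names(profile)) "z" else "value"
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$x, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "cross-sectional position (um)",
                  y = if (ycol == "z") "depth (um)" else "mean signal") +
    ggplot2::theme_minimal()
  if (ycol == "z") p <- p + ggplot2::scale_y_reverse()
  if (!is.null(grooves) && nrow(grooves) > 0) {
    p <- p + ggplot2::geom_rect(
      data = grooves,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    )
  }
  p
}

#' Plot per-architecture group means with standard errors
#'
#' Bar chart of mean DOA / DOC per architecture with SEM error bars and the
#' y = 1 reference line (random alignment for DOA, uniform distribution for
#' DOC).
#'
#' @param summary tibble from [summarize_groups()].
#' @return A ggplot.
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$architecture, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean (error bars: SEM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
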