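# ggplot2 visualisations for the main result types.

#' Plot threshold profiles as an audiogram
#'
#' Standard audiometric layout: log-spaced frequency axis, dB HL increasing
#' downward, one line per (ear, conduction).
#'
#' @param profiles Long threshold tibble.
#' @return A ggplot object.
#' @export
plot_audiogram <- function(profiles) {
  ggplot2::ggplot(
    filter(profiles, !is.na(.data$threshold_db)),
    ggplot2::aes(x = .data$frequency_hz, y = .data$threshold_db,
                 shape = .data$ear, linetype = .data$conduction,
                 group = interaction(.data$subject_id, .data$ear,
                                     .data$conduction))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10(breaks = sort(unique(profiles$frequency_hz))) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frequency (Hz)", y = "hearing level (dB HL)") +
    ggplot2::theme_minimal()
}

#' Display a rendered chart image (optionally with its truth sidecar)
#'
#' @param package A `chart_package` from [render_chart()].
#' @param truth Overlay the ground-truth symbol centers.
#' @return A ggplot object.
#' @export
plot_chart <- function(package, truth = FALSE) {
  img <- package$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- as.numeric(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (truth) {
    p <- p + ggplot2::geom_point(
      data = package$truth,
      ggplot2::aes(.data$x, .data$y, color = .data$class),
      inherit.aes = FALSE, shape = 1, size = 4)
  }
  p
}

#' @export
autoplot.aud_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aud_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report$per_class,
                              cols = c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aud_logistic <- function(object, ...) {
  imp <- feature_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$magnitude),
    y = .data$magnitude)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|coefficient|") +
    ggplot2::theme_minimal()
}
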