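#' Plot a log-Mel spectrogram
#'
#' @param object A `mel_spectrogram` from [mel_spectrogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mel_spectrogram
#' @export
autoplot.mel_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    time_s = attr(object, "times"),
    mel_center_hz = attr(object, "centers_hz")
  )
  df$log_energy <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mel_center_hz,
                                   fill = .data$log_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "Mel filter center (Hz)",
                  fill = "log energy") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix heatmap
#'
#' Truth on rows, prediction on columns, count and percentage per cell —
#' the usual presentation of a per-task activity classifier.
#'
#' @param object A `classifier_report` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- tidy(object)
  df$pct <- 100 * df$count / sum(df$count)
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f%%)", .data$count, .data$pct))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s: accuracy %.2f%%, error %.2f%%",
                      object$phase, object$accuracy, object$error),
      x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot recovered mating events on a timeline
#'
#' @param object A `mating_events` table from [segment_mating()].
#' @param truth Optional ground-truth tibble with `event_start_s`,
#'   `event_end_s` (drawn above the recovered events).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mating_events
#' @export
autoplot.mating_events <- function(object, truth = NULL, ...) {
  debug <- attr(object, "debug")
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = debug,
                       ggplot2::aes(.data$time_s, as.integer(.data$overlap)),
                       color = "grey60") +
    ggplot2::labs(x = "time (s)", y = "overlap flag") +
    ggplot2::theme_minimal()
  if (nrow(object)) {
    p <- p + ggplot2::geom_segment(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$start_s, xend = .data$end_s, y = 1.1, yend = 1.1),
      linewidth = 3, color = "firebrick")
  }
  if (!is.null(truth) && nrow(truth)) {
    p <- p + ggplot2::geom_segment(
      data = truth,
      ggplot2::aes(x = .data$event_start_s, xend = .data$event_end_s,
                   y = 1.2, yend = 1.2),
      linewidth = 3, color = "darkgreen")
  }
  p
}

#' Plot per-task accuracies of an audio run
#'
#' @param object An `audio_run` from [run_audio_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot audio_run
#' @export
autoplot.audio_run <- function(object, ...) {
  ggplot2::ggplot(object$reports,
                  ggplot2::aes(.data$task, .data$accuracy, fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
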