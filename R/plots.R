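#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recording
#'
#' Channel traces over time, facetted per channel. Long recordings are
#' thinned to at most `max_points` samples per channel for drawing.
#'
#' @param object An [emg_recording()].
#' @param channels Optional subset of channel labels.
#' @param max_points Per-channel point budget (default 5000).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_recording
#' @export
autoplot.emg_recording <- function(object, channels = NULL,
                                   max_points = 5000L, ...) {
  df <- as_tibble.emg_recording(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  step <- max(1L, floor(n_samples(object) / max_points))
  df <- dplyr::filter(df, (round(.data$time * object$rate)) %% step == 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "voltage (V)") +
    ggplot2::theme_minimal()
}

#' Plot separated components
#'
#' @param object An `unmixing_result`.
#' @param rate Sampling rate in Hz used for the time axis (default 1).
#' @inheritParams autoplot.emg_recording
#' @return A ggplot of the component traces.
#' @method autoplot unmixing_result
#' @export
autoplot.unmixing_result <- function(object, rate = 1, max_points = 5000L, ...) {
  S <- object$components
  autoplot.emg_recording(
    emg_recording(S, rate, paste0("IC", seq_len(ncol(S)))),
    max_points = max_points
  )
}

#' Confusion-matrix heatmap
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot tile map, true classes on rows.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$confusion)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum
#'
#' @param object A `spectrum_estimate`.
#' @param ... Unused.
#' @return A ggplot line plot of amplitude against frequency.
#' @method autoplot spectrum_estimate
#' @export
autoplot.spectrum_estimate <- function(object, ...) {
  df <- tibble::tibble(freq = object$freqs, amplitude = object$amplitudes)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Bar chart of a device-agreement report
#'
#' @param report Tibble from [compare_recordings()].
#' @return A ggplot with one bar group per movement.
#' @export
plot_agreement <- function(report) {
  df <- tidyr::pivot_longer(report, -"movement", names_to = "metric",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$movement, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "agreement") +
    ggplot2::theme_minimal()
}
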