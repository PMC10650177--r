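#' Multichannel sEMG recording
#'
#' A recording holds a channels-in-columns voltage matrix sampled at a fixed
#' rate, plus channel labels and (optionally) the ADC configuration it came
#' from. Rows are sample instants, matching the on-disk text layout used by
#' [write_recording()].
#'
#' @param samples Numeric matrix, rows = sample instants, columns = channels.
#'   A vector is treated as a single channel.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector naming the channels;
#'   defaults to `L1..L8, R1..R8`-style labels for 16 channels, `ch1..chK`
#'   otherwise.
#' @param adc Optional [adc_config()] provenance.
#'
#' @return An object of class `emg_recording`.
#' @export
#' @examples
#' rec <- emg_recording(cbind(sin(1:100), cos(1:100)), rate = 1000)
#' rec
emg_recording <- function(samples, rate, channel_labels = NULL, adc = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) < 1L) stop("recording must have at least one channel")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (is.null(channel_labels)) channel_labels <- default_channel_labels(ncol(samples))
  if (length(channel_labels) != ncol(samples)) {
    stop("`channel_labels` length must equal the channel count")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, rate = as.numeric(rate),
         channel_labels = as.character(channel_labels), adc = adc),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
    n_channels(x), n_samples(x), x$rate, n_samples(x) / x$rate
  ))
  cat("channels:", paste(utils::head(x$channel_labels, 8L), collapse = ", "),
      if (n_channels(x) > 8L) "..." else "", "\n")
  invisible(x)
}

default_channel_labels <- function(k) {
  if (k == 16L) {
    c(paste0("L", 1:8), paste0("R", 1:8))
  } else {
    paste0("ch", seq_len(k))
  }
}

#' Number of channels / samples in a recording
#' @param x An `emg_recording`.
#' @return Integer count.
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname n_channels
#' @export
n_samples <- function(x) nrow(x$samples)

#' @export
as.matrix.emg_recording <- function(x, ...) x$samples

#' Tidy view of a recording
#'
#' Long-format tibble with one row per (time, channel) sample, convenient for
#' dplyr/ggplot2 work on short segments.
#'
#' @param x An `emg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `channel`, `value` (V).
#' @method as_tibble emg_recording
#' @export
as_tibble.emg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep((seq_len(n_samples(x)) - 1) / x$rate, times = n_channels(x)),
    channel = factor(rep(x$channel_labels, each = n_samples(x)),
                     levels = x$channel_labels),
    value = as.vector(x$samples)
  )
}

#' Extract a contiguous slice of a recording
#'
#' @param x An `emg_recording`.
#' @param from,to 1-based first and last sample indices (inclusive).
#' @return An `emg_recording` covering the requested window.
#' @export
slice_recording <- function(x, from, to) {
  stopifnot(inherits(x, "emg_recording"))
  if (from < 1L || to > n_samples(x) || from > to) {
    stop("slice window [", from, ", ", to, "] outside recording of ",
         n_samples(x), " samples")
  }
  emg_recording(x$samples[from:to, , drop = FALSE], x$rate,
                x$channel_labels, x$adc)
}

# apply a per-channel function (vector -> vector of same length), keep metadata
map_channels <- function(x, f, ...) {
  out <- apply(x$samples, 2L, f, ...)
  if (is.null(dim(out))) out <- matrix(out, ncol = n_channels(x))
  emg_recording(out, x$rate, x$channel_labels, x$adc)
}
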