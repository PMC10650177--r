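#' sEMG conditioning chain
#'
#' The standard conditioning stages for surface EMG, applied per channel and,
#' by default, in zero-phase (forward-backward) mode so that burst timing is
#' preserved. Stage order in [preprocess_chain()] is: powerline notch,
#' 20-350 Hz Butterworth band-pass, DC removal, full-wave rectification,
#' low-pass linear envelope.
#'
#' @name preprocess
NULL

apply_filter <- function(recording, b, a, zero_phase = TRUE) {
  filt <- signal::Arma(b = b, a = a)
  map_channels(recording, function(x) {
    if (zero_phase) signal::filtfilt(filt, x) else
      as.numeric(signal::filter(filt, x))
  })
}

# second-order IIR notch (constrained biquad): unity gain away from f0,
# null at f0, -3 dB width f0/quality.
notch_coefficients <- function(freq, rate, quality) {
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * quality)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Powerline notch filter
#'
#' Narrow band-stop at the mains frequency. With the default quality factor
#' the designed response is at least 30 dB down at `freq` while frequencies
#' 10 Hz away are within 1 dB of unity (zero-phase mode doubles the dB
#' attenuation).
#'
#' @param recording An [emg_recording()].
#' @param freq Notch frequency in Hz (< Nyquist); default 50.
#' @param quality Quality factor `f0 / bandwidth`; default 30.
#' @param zero_phase Apply forward-backward for zero group delay (default).
#' @return Filtered [emg_recording()].
#' @export
notch <- function(recording, freq = 50, quality = 30, zero_phase = TRUE) {
  check_below_nyquist(freq, recording$rate)
  co <- notch_coefficients(freq, recording$rate, quality)
  apply_filter(recording, co$b, co$a, zero_phase)
}

check_below_nyquist <- function(freq, rate, what = "frequency") {
  if (any(freq >= rate / 2) || any(freq <= 0)) {
    stop(what, " must lie strictly inside (0, rate/2)")
  }
}

#' Butterworth band-pass
#'
#' Fourth-order band-pass in the Matlab/signal convention (`butter(4, c(lo,
#' hi))`, an order-8 recursive filter), -3 dB at each corner in single-pass
#' mode. The 20-350 Hz default keeps the main sEMG energy band.
#'
#' @inheritParams notch
#' @param low,high Corner frequencies in Hz, `0 < low < high < rate/2`.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered [emg_recording()].
#' @export
bandpass <- function(recording, low = 20, high = 350, order = 4,
                     zero_phase = TRUE) {
  if (!(low > 0 && low < high && high < recording$rate / 2)) {
    stop("band corners must satisfy 0 < low < high < rate/2")
  }
  bf <- signal::butter(order, c(low, high) / (recording$rate / 2), type = "pass")
  apply_filter(recording, bf$b, bf$a, zero_phase)
}

#' Remove per-channel DC
#'
#' Subtracts each channel's mean.
#'
#' @inheritParams notch
#' @return [emg_recording()] with zero-mean channels.
#' @export
remove_dc <- function(recording) {
  map_channels(recording, function(x) x - mean(x))
}

#' Full-wave rectification
#'
#' Element-wise absolute value, highlighting amplitude variation before
#' envelope extraction.
#'
#' @inheritParams notch
#' @return Rectified [emg_recording()].
#' @export
rectify <- function(recording) {
  map_channels(recording, abs)
}

#' Linear envelope
#'
#' Second-order Butterworth low-pass (default 10 Hz cutoff) smoothing the
#' rectified signal into a linear envelope. Because a recursive low-pass can
#' ring slightly, small negative excursions in the output are possible and
#' are not clipped.
#'
#' @inheritParams notch
#' @param cutoff Low-pass cutoff in Hz (< Nyquist); default 10.
#' @return Smoothed [emg_recording()].
#' @export
envelope <- function(recording, cutoff = 10, zero_phase = TRUE) {
  check_below_nyquist(cutoff, recording$rate, "cutoff")
  bf <- signal::butter(2, cutoff / (recording$rate / 2), type = "low")
  apply_filter(recording, bf$b, bf$a, zero_phase)
}

#' Composed conditioning chain
#'
#' Applies notch, band-pass, DC removal, full-wave rectification and the
#' envelope low-pass in that order. Set `keep_stages = TRUE` to retain each
#' intermediate recording for inspection.
#'
#' @inheritParams notch
#' @param notch_freq,notch_quality Notch parameters.
#' @param low,high,order Band-pass parameters.
#' @param envelope_cutoff Envelope low-pass cutoff in Hz.
#' @param keep_stages Return intermediates as attribute `stages`.
#' @return The chain output [emg_recording()]; with `keep_stages`, attribute
#'   `stages` holds the named list of intermediates.
#' @export
preprocess_chain <- function(recording, notch_freq = 50, notch_quality = 30,
                             low = 20, high = 350, order = 4,
                             envelope_cutoff = 10, zero_phase = TRUE,
                             keep_stages = FALSE) {
  s1 <- notch(recording, notch_freq, notch_quality, zero_phase)
  s2 <- bandpass(s1, low, high, order, zero_phase)
  s3 <- remove_dc(s2)
  s4 <- rectify(s3)
  s5 <- envelope(s4, envelope_cutoff, zero_phase)
  if (keep_stages) {
    attr(s5, "stages") <- list(notch = s1, bandpass = s2, dc_removed = s3,
                               rectified = s4, envelope = s5)
  }
  s5
}
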