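#' ADC configuration
#'
#' Describes the delta-sigma front end: 24-bit resolution, programmable gain
#' (default 24) and reference voltage. The least significant bit corresponds
#' to `vref / (gain * (2^23 - 1))` volts at the electrode.
#'
#' @param resolution_bits ADC resolution; fixed at 24 for this device family.
#' @param gain Programmable amplifier gain (> 0), default 24.
#' @param vref Reference voltage in volts (> 0), default 4.5.
#' @param sps Samples per second; must lie in \[250, 16000\].
#'
#' @return An object of class `adc_config`.
#' @export
adc_config <- function(resolution_bits = 24L, gain = 24, vref = 4.5, sps = 1000) {
  if (resolution_bits != 24L) stop("only 24-bit resolution is supported")
  if (gain <= 0) stop("`gain` must be > 0")
  if (vref <= 0) stop("`vref` must be > 0")
  if (sps < 250 || sps > 16000) stop("`sps` must lie in [250, 16000]")
  structure(list(resolution_bits = 24L, gain = gain, vref = vref, sps = sps),
            class = "adc_config")
}

#' Raw acquisition throughput
#'
#' Data volume produced per second, `D = N * fs * R`, for `N` channels sampled
#' at `fs` Hz with `R` bits per sample (24-bit codes are widened to 32 bits on
#' the wire). 16 channels at 1 kHz and 32 bits give 512,000 bits/s (512 Kb/s).
#'
#' @param n_channels Number of data channels (> 0).
#' @param sampling_freq Sampling frequency in Hz (> 0).
#' @param bits_per_sample Bits generated per channel per sample (> 0).
#'
#' @return Throughput in bits per second.
#' @export
#' @examples
#' data_rate(16, 1000, 32)  # 512000
data_rate <- function(n_channels, sampling_freq, bits_per_sample) {
  if (any(c(n_channels, sampling_freq, bits_per_sample) <= 0)) {
    stop("all arguments to data_rate() must be positive")
  }
  n_channels * sampling_freq * bits_per_sample
}

adc_full_scale_code <- 2^23 - 1

#' Convert ADC codes to volts and back
#'
#' Uses the delta-sigma convention `volts = code * vref / (gain * (2^23 - 1))`,
#' so positive full scale maps to `vref / gain`. `volts_to_code()` rounds to
#' the nearest code and is the inverse up to one least significant bit.
#'
#' @param code Integer code(s) in `[-2^23, 2^23 - 1]` (two's complement range).
#' @param volts Voltage(s) within the input range `vref / gain`.
#' @param adc An [adc_config()].
#'
#' @return Volts (`code_to_volts`) or integer-valued codes (`volts_to_code`).
#' @export
#' @examples
#' code_to_volts(2^23 - 1, adc_config())  # 4.5 / 24 = 0.1875 V
code_to_volts <- function(code, adc = adc_config()) {
  if (any(code < -2^23 | code > 2^23 - 1)) {
    stop("code out of 24-bit two's-complement range")
  }
  code * adc$vref / (adc$gain * adc_full_scale_code)
}

#' @rdname code_to_volts
#' @export
volts_to_code <- function(volts, adc = adc_config()) {
  code <- round(volts * adc$gain * adc_full_scale_code / adc$vref)
  pmin(pmax(code, -2^23), 2^23 - 1)
}

#' Write a recording to the plain-text dialect
#'
#' Whitespace-separated volts, one row per sample instant and one column per
#' channel, preceded by `#`-prefixed metadata lines (`rate`, `channels`, and
#' `gain` when ADC provenance is present). [read_recording()] restores values
#' to the printed precision (15 significant digits) and all metadata.
#'
#' @param recording An [emg_recording()].
#' @param path File path to write / read.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [emg_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate: %.10g", recording$rate),
    sprintf("# channels: %s", paste(recording$channel_labels, collapse = " ")),
    if (!is.null(recording$adc)) sprintf("# gain: %.10g", recording$adc$gain)
  ), con)
  utils::write.table(
    format(recording$samples, digits = 15, scientific = TRUE, trim = TRUE),
    con, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  rate <- get_field("rate")
  if (is.null(rate)) stop("recording file lacks a '# rate:' header line")
  labels <- get_field("channels")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("recording file contains no samples")
  rows <- strsplit(trimws(body), "\\s+")
  k <- length(rows[[1]])
  if (any(lengths(rows) != k)) stop("ragged rows in recording file")
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop("non-numeric cell in recording file")
  mat <- matrix(vals, ncol = k, byrow = TRUE)
  gain <- get_field("gain")
  adc <- if (!is.null(gain)) adc_config(gain = as.numeric(gain)) else NULL
  emg_recording(mat, as.numeric(rate),
                if (!is.null(labels)) strsplit(labels, "\\s+")[[1]] else NULL,
                adc)
}
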