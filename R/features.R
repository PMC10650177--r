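#' Time-domain sEMG features
#'
#' The five classic amplitude features of a component epoch, evaluated exactly
#' as defined:
#' \itemize{
#'   \item IEMG: `sum(|x_i|)`
#'   \item VAR: `mean((x_i - mean(x))^2)` (population 1/N form)
#'   \item MAV: `mean(|x_i|)`
#'   \item SSI: `sum(x_i^2)`
#'   \item RMS: `sqrt(mean(x_i^2))`
#' }
#' By construction `IEMG = N * MAV` and `SSI = N * RMS^2` exactly.
#'
#' @param samples Numeric vector, length N >= 1.
#' @return A named list: `iemg`, `var`, `mav`, `ssi`, `rms`.
#' @export
#' @examples
#' time_domain_features(c(1, -2, 3))
time_domain_features <- function(samples) {
  n <- length(samples)
  if (n < 1L) stop("empty input")
  if (!all(is.finite(samples))) stop("samples must be finite")
  list(
    iemg = sum(abs(samples)),
    var = mean((samples - mean(samples))^2),
    mav = mean(abs(samples)),
    ssi = sum(samples^2),
    rms = sqrt(mean(samples^2))
  )
}

#' Amplitude spectrum of an epoch
#'
#' Single discrete-transform magnitude spectrum of the mean-detrended epoch on
#' `[0, rate/2]`, amplitude convention `2|X(f)|/N` (so a pure sinusoid of
#' amplitude a shows a peak of about a). No segment averaging; the estimator
#' tag records the method.
#'
#' @param samples Numeric vector, length >= 2.
#' @param rate Sampling rate in Hz.
#' @return An object of class `spectrum_estimate`: tibble-backed list with
#'   `freqs` (Hz, ascending), `amplitudes` (>= 0), `method`.
#' @export
power_spectrum <- function(samples, rate) {
  n <- length(samples)
  if (n < 2L) stop("need at least two samples for a spectrum")
  x <- samples - mean(samples)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  amp <- 2 * Mod(X[half]) / n
  amp[1] <- Mod(X[1]) / n
  if (n %% 2 == 0) amp[length(half)] <- Mod(X[length(half)]) / n
  structure(list(freqs = (half - 1) * rate / n, amplitudes = amp,
                 method = "single-fft magnitude"),
            class = "spectrum_estimate")
}

#' Frequency-domain sEMG features
#'
#' From an amplitude spectrum `S(n)` at frequencies `f_n`:
#' \itemize{
#'   \item FC (centroid frequency): `sum(f_n S(n)) / sum(S(n))`
#'   \item MF: `sum(S(n)) / N`, i.e. the *mean spectral amplitude* exactly as
#'     defined (note this is not the median frequency that "MF" often denotes
#'     elsewhere; units are spectrum-amplitude units, not Hz)
#'   \item FRMS (root-mean-square frequency):
#'     `sqrt(sum(f_n^2 S(n)) / sum(S(n)))`
#' }
#' FC and FRMS are spectral moments, so `FRMS >= FC` always (Cauchy-Schwarz)
#' and both lie within the frequency support. An all-zero spectrum leaves FC
#' and FRMS undefined and raises an error; MF is 0 there.
#'
#' @param spectrum A [power_spectrum()] result (or list with `freqs`,
#'   `amplitudes`).
#' @return A named list: `fc`, `mf`, `frms`.
#' @export
frequency_domain_features <- function(spectrum) {
  f <- spectrum$freqs; s <- spectrum$amplitudes
  if (length(f) != length(s)) stop("freqs and amplitudes differ in length")
  if (any(s < 0)) stop("spectrum amplitudes must be non-negative")
  tot <- sum(s)
  mf <- tot / length(s)
  if (tot == 0) stop("all-zero spectrum: FC and FRMS are undefined (MF would be 0)")
  list(fc = sum(f * s) / tot, mf = mf, frms = sqrt(sum(f^2 * s) / tot))
}

feature_names <- c("iemg", "var", "mav", "ssi", "rms", "fc", "mf", "frms")

#' Feature vector of one component epoch
#'
#' All eight features of one component signal.
#'
#' @param samples Numeric vector (one component, one epoch).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of the 8 features, in fixed order
#'   `iemg, var, mav, ssi, rms, fc, mf, frms`.
#' @export
component_features <- function(samples, rate) {
  td <- time_domain_features(samples)
  fd <- frequency_domain_features(power_spectrum(samples, rate))
  unlist(c(td, fd))[feature_names]
}

#' Epoch x feature matrix
#'
#' Computes the 8 features for every component of every epoch, producing one
#' row per epoch with `8 * n_components` feature columns named
#' `c{k}_{feature}` in fixed order (component-major), plus the label columns
#' of `epochs`. With the default 8 components this is the 64-dimensional
#' representation used for movement classification. Features are computed on
#' the whole epoch (no sub-windowing).
#'
#' @param components Time x n_components matrix of component signals covering
#'   the full session (e.g. from [separate()]).
#' @param epochs Labeled epoch tibble with `onset_sample` and
#'   `duration_samples` (plus `action` / `intensity` labels, kept).
#' @param rate Sampling rate in Hz.
#' @return A tibble: label columns from `epochs`, then the feature columns.
#' @export
extract_feature_matrix <- function(components, epochs, rate) {
  components <- as.matrix(components)
  k <- ncol(components)
  segs <- epoch_segments(components, epochs)
  feat <- lapply(segs, function(seg) {
    unlist(lapply(seq_len(k), function(j) component_features(seg[, j], rate)))
  })
  M <- do.call(rbind, feat)
  colnames(M) <- as.vector(t(outer(seq_len(k), feature_names,
                                   function(i, f) paste0("c", i, "_", f))))
  if (anyNA(M)) stop("missing values in feature matrix")
  dplyr::bind_cols(tibble::as_tibble(epochs), tibble::as_tibble(M))
}

#' Names of the feature columns in a feature matrix
#' @param feature_matrix A tibble from [extract_feature_matrix()].
#' @return Character vector of the `c{k}_{feature}` columns.
#' @export
feature_columns <- function(feature_matrix) {
  grep("^c[0-9]+_(iemg|var|mav|ssi|rms|fc|mf|frms)$", names(feature_matrix),
       value = TRUE)
}

#' Read and write feature matrices as TSV
#' @param feature_matrix Tibble from [extract_feature_matrix()].
#' @param path File path.
#' @return `read_features()` returns a tibble.
#' @export
write_features <- function(feature_matrix, path) {
  utils::write.table(feature_matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
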