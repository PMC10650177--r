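#' Spearman rank correlation
#'
#' Rank-based Pearson correlation with average ranks for ties, in
#' \[-1, 1\]; invariant under strictly monotone transforms of either input.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), neither constant.
#' @return The coefficient.
#' @export
spearman <- function(x, y) {
  check_pair(x, y)
  stats::cor(x, y, method = "spearman")
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("signals differ in length")
  if (length(x) < 2L) stop("need at least two samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant signal")
  }
}

#' Signal energy and energy ratio
#'
#' Energy is the Riemann sum `sum(x^2) * dt` approximating the integral of
#' the squared signal. The ratio of two signals' energies is reported as
#' `min(E_x, E_y) / max(E_x, E_y)`, a symmetric similarity in \[0, 1\] that
#' is 1 for identical energies.
#'
#' @param x,y Numeric signals (equal length for the ratio).
#' @param dt Sample interval in seconds (> 0).
#' @return `energy()` a scalar in signal-units^2 * s; `energy_ratio()` a
#'   value in \[0, 1\].
#' @export
energy <- function(x, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  sum(x^2) * dt
}

#' @rdname energy
#' @export
energy_ratio <- function(x, y, dt = 1) {
  if (length(x) != length(y)) stop("signals differ in length")
  ex <- energy(x, dt); ey <- energy(y, dt)
  if (ex == 0 && ey == 0) stop("energy ratio undefined for two zero signals")
  min(ex, ey) / max(ex, ey)
}

#' Linear correlation coefficient
#'
#' The centered product-moment sum formula
#' `sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`,
#' in \[-1, 1\] and invariant to positive-slope affine maps of either input.
#'
#' @inheritParams spearman
#' @return The coefficient.
#' @export
lcc <- function(x, y) {
  check_pair(x, y)
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Cross-correlation coefficient
#'
#' At lag 0 this is the normalized cross-correlation sum formula
#' `(n sum(xy) - sum(x) sum(y)) / sqrt((n sum(x^2) - sum(x)^2)(n sum(y^2) - sum(y)^2))`,
#' which is algebraically identical to [lcc()]. With `max_lag > 0` the
#' coefficient is maximized over integer shifts of `y` (overlapping part
#' only) and the best lag is attached as attribute `lag`.
#'
#' @inheritParams spearman
#' @param max_lag Non-negative integer; 0 (default) evaluates lag 0 only.
#' @return The coefficient (with attribute `lag` when `max_lag > 0`).
#' @export
ccc <- function(x, y, max_lag = 0L) {
  check_pair(x, y)
  ccc0 <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    num / den
  }
  if (max_lag == 0L) return(ccc0(x, y))
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(L) {
    if (L >= 0) {
      xs <- x[seq_len(length(x) - L)]
      ys <- y[L + seq_len(length(y) - L)]
    } else {
      xs <- x[-L + seq_len(length(x) + L)]
      ys <- y[seq_len(length(y) + L)]
    }
    if (length(xs) < 2L || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(NA_real_)
    }
    ccc0(xs, ys)
  }, numeric(1))
  best <- which.max(vals)
  structure(vals[best], lag = lags[best])
}

#' Per-movement device-agreement report
#'
#' Computes all four agreement statistics for each movement's aligned signal
#' pair, returning one tidy row per movement (the two-device comparison table
#' shape).
#'
#' @param pairs A tibble/data frame with columns `movement` (label), `x` and
#'   `y` (list columns of equal-length numeric signals).
#' @param dt Sample interval in seconds for the energy ratio.
#' @return A tibble: `movement`, `spearman`, `energy_ratio`, `lcc`, `ccc`.
#' @export
#' @examples
#' sig <- sin(seq(0, 4 * pi, length.out = 200))
#' compare_recordings(tibble::tibble(
#'   movement = "frown", x = list(sig), y = list(sig * 1.1)
#' ))
compare_recordings <- function(pairs, dt = 1e-3) {
  stopifnot(all(c("movement", "x", "y") %in% names(pairs)))
  purrr::pmap_dfr(pairs, function(movement, x, y, ...) {
    tibble::tibble(
      movement = movement,
      spearman = spearman(x, y),
      energy_ratio = energy_ratio(x, y, dt),
      lcc = lcc(x, y),
      ccc = as.numeric(ccc(x, y))
    )
  })
}
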