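#' Whiten a multichannel recording
#'
#' PCA whitening: centers each channel, projects onto the leading
#' `n_components` principal directions and rescales them to unit variance, so
#' the output components are mutually uncorrelated with identity covariance.
#' The transform is recorded for later inversion, and reducing 16 channels to
#' 8 components happens here.
#'
#' @param recording An [emg_recording()] or a time x channels matrix.
#' @param n_components Number of components to keep (<= channel count).
#' @param rank_tol Relative eigenvalue tolerance below which a direction is
#'   treated as numerically null.
#' @return A list: `z` (time x n_components whitened matrix), `K`
#'   (n_components x channels whitening matrix), `means` (channel means),
#'   `dewhiten` (channels x n_components inverse transform), `eigenvalues`.
#' @export
whiten <- function(recording, n_components, rank_tol = 1e-10) {
  X <- if (inherits(recording, "emg_recording")) recording$samples else as.matrix(recording)
  k <- ncol(X)
  if (n_components > k) stop("n_components exceeds the channel count")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  d <- eg$values
  if (d[n_components] <= rank_tol * max(d[1], .Machine$double.eps)) {
    stop("input is rank deficient: fewer than ", n_components,
         " directions with nonzero variance")
  }
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  dk <- d[seq_len(n_components)]
  K <- diag(1 / sqrt(dk), n_components) %*% t(E)
  list(z = Xc %*% t(K), K = K, means = mu,
       dewhiten = E %*% diag(sqrt(dk), n_components), eigenvalues = d)
}

sym_decorrelate <- function(W) {
  eg <- eigen(W %*% t(W), symmetric = TRUE)
  s <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, .Machine$double.eps)),
                           nrow(W)) %*% t(eg$vectors)
  s %*% W
}

#' Fit a blind source separation model
#'
#' Estimates the unmixing matrix by a fixed-point iteration with the log-cosh
#' contrast and symmetric decorrelation, after PCA whitening to
#' `n_components`. Deterministic given `seed`. The separated sources are only
#' identifiable up to sign, scale and permutation; the fit canonicalizes them
#' to unit variance, positive peak sample, and decreasing explained input
#' variance.
#'
#' @param recording An [emg_recording()] or time x channels matrix.
#' @param n_components Number of sources to estimate (default 8).
#' @param seed Integer seed for the rotation initialization.
#' @param max_iter Fixed-point iteration cap per restart (default 400).
#' @param tol Convergence tolerance on the rotation update (default 1e-5).
#' @param restarts Independent random initializations (default 3); the run
#'   whose components deviate most from Gaussianity under the log-cosh
#'   contrast is kept. The fixed-point surface of burst-structured signals is
#'   shallow and a single run can settle in a rotated local optimum.
#' @return An object of class `unmixing_result`: `W` (the full
#'   n_components x channels unmixing map including whitening), `rotation`
#'   (the square orthogonal factor), `whitening`, `means`, `mixing_estimate`
#'   (channels x n_components), `components` (time x n_components),
#'   `n_components`, `converged`, `iterations`. A warning (not an error) is
#'   raised when no restart converges within `max_iter`, which is expected
#'   for e.g. purely Gaussian sources.
#' @export
fit_ica <- function(recording, n_components = 8, seed = 1L,
                    max_iter = 400L, tol = 1e-5, restarts = 3L) {
  wh <- whiten(recording, n_components)
  Z <- wh$z
  n <- nrow(Z)
  if (n < 2L * n_components) stop("too few samples to estimate ", n_components,
                                  " components")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  # E[log cosh(u)] for u ~ N(0, 1), the Gaussian baseline of the contrast
  gauss_logcosh <- 0.3745672
  runs <- lapply(seq_len(restarts), function(r) {
    set.seed(derive_seed(seed, 77L + r))
    W <- sym_decorrelate(matrix(stats::rnorm(n_components^2), n_components))
    converged <- FALSE
    it <- 0L
    delta <- Inf
    while (it < max_iter) {
      it <- it + 1L
      U <- Z %*% t(W)            # time x k, current source estimates
      G <- tanh(U)
      W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), n_components) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    U <- Z %*% t(W)
    obj <- sum((colMeans(log(cosh(U))) - gauss_logcosh)^2)
    list(W = W, converged = converged, iterations = it, delta = delta,
         objective = obj)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "objective"))]]
  W <- best$W
  converged <- best$converged
  it <- best$iterations
  if (!converged) {
    warning("ICA did not converge within ", max_iter,
            " iterations (last update ", signif(best$delta, 3), ")")
  }
  S <- Z %*% t(W)
  A_hat <- wh$dewhiten %*% t(W)          # channels x k mixing estimate
  # canonicalize: unit variance, positive peak, order by explained variance
  sds <- apply(S, 2L, stats::sd)
  sds[sds == 0] <- 1
  S <- sweep(S, 2L, sds, `/`)
  A_hat <- sweep(A_hat, 2L, sds, `*`)
  W <- sweep(W, 1L, sds, `/`)
  signs <- vapply(seq_len(ncol(S)), function(j) {
    s <- sign(S[which.max(abs(S[, j])), j]); if (s == 0) 1 else s
  }, numeric(1))
  S <- sweep(S, 2L, signs, `*`)
  A_hat <- sweep(A_hat, 2L, signs, `*`)
  W <- sweep(W, 1L, signs, `*`)
  ord <- order(colSums(A_hat^2), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  A_hat <- A_hat[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]
  structure(list(
    W = W %*% wh$K, rotation = W, whitening = wh$K, means = wh$means,
    mixing_estimate = A_hat, components = S, n_components = n_components,
    converged = converged, iterations = it, tol = tol
  ), class = "unmixing_result")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf("<unmixing_result> %d components, %s after %d iteration(s)\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Apply a fitted unmixing map to (new) data
#'
#' Pure linear map `s(t) = W x(t)` using the stored whitening and channel
#' means, so a session's fit can be replayed on any recording with matching
#' channels.
#'
#' @param recording An [emg_recording()] or time x channels matrix.
#' @param result An `unmixing_result`.
#' @return Time x n_components numeric matrix of component signals.
#' @export
separate <- function(recording, result) {
  X <- if (inherits(recording, "emg_recording")) recording$samples else as.matrix(recording)
  if (ncol(X) != ncol(result$W)) {
    stop("channel count (", ncol(X), ") does not match the unmixing matrix (",
         ncol(result$W), ")")
  }
  sweep(X, 2L, result$means) %*% t(result$W)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' map and a true mixing matrix. `P = W_full %*% A` is identity-like (one
#' dominant entry per row and column) when separation is perfect, giving an
#' index of 0; the normalization keeps the index in \[0, 1\] with 1 the
#' worst case.
#'
#' @param W_full n_components x channels unmixing map (including whitening).
#' @param A channels x n_components true mixing matrix.
#' @return The Amari index in \[0, 1\].
#' @export
amari_index <- function(W_full, A) {
  P <- abs(W_full %*% A)
  n <- nrow(P)
  if (n != ncol(P)) stop("W %*% A must be square")
  rows <- sum(rowSums(P) / apply(P, 1L, max) - 1)
  cols <- sum(colSums(P) / apply(P, 2L, max) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

#' Match estimated components to true sources
#'
#' Greedy sign/permutation-invariant matching by absolute correlation: the
#' highest |correlation| pair is assigned first, then removed, and so on.
#'
#' @param components Time x k matrix of estimated components.
#' @param sources Time x m matrix of true source signals (m <= k).
#' @return A tibble with `source`, `component`, `correlation` (absolute).
#' @export
match_components <- function(components, sources) {
  components <- as.matrix(components); sources <- as.matrix(sources)
  src_idx <- which(apply(sources, 2L, stats::sd) > 0)
  comp_idx <- seq_len(ncol(components))
  R <- abs(stats::cor(sources[, src_idx, drop = FALSE], components))
  out <- list()
  while (length(src_idx) > 0 && length(comp_idx) > 0) {
    ij <- arrayInd(which.max(R), dim(R))
    out[[length(out) + 1L]] <- tibble::tibble(
      source = src_idx[ij[1]], component = comp_idx[ij[2]],
      correlation = R[ij[1], ij[2]]
    )
    R <- R[-ij[1], -ij[2], drop = FALSE]
    src_idx <- src_idx[-ij[1]]
    comp_idx <- comp_idx[-ij[2]]
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
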