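test_that("whitening produces identity covariance and a recorded transform", {
  set.seed(8)
  X <- matrix(stats::rnorm(4000), 1000, 4) %*% matrix(stats::rnorm(16), 4, 4)
  wh <- whiten(X, 4)
  expect_equal(stats::cov(wh$z), diag(4), tolerance = 1e-8)
  # the transform inverts: dewhiten %*% K recovers the centering projection
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(wh$z %*% t(wh$dewhiten), Xc, tolerance = 1e-8)
  # already-white data: transform is (close to) a rotation
  Zw <- matrix(stats::rnorm(20000), 10000, 2)
  whw <- whiten(Zw, 2)
  expect_equal(t(whw$K) %*% whw$K, diag(2), tolerance = 0.1)
})

test_that("rank deficiency below the requested components is an error", {
  set.seed(3)
  X <- matrix(stats::rnorm(3000), 1000, 3)
  X <- cbind(X, X[, 3])                       # duplicated channel
  expect_error(whiten(X, 4), "rank deficient")
  expect_error(whiten(X, 5), "exceeds")
})

test_that("separate() is the stated linear map", {
  set.seed(5)
  X <- matrix(stats::rnorm(600), 200, 3)
  res <- structure(list(W = diag(3), means = rep(0, 3)),
                   class = "unmixing_result")
  expect_equal(separate(X, res), X)
  expect_true(all(separate(matrix(0, 50, 3), res) == 0))
  # brute-force per-sample dot-product oracle for an arbitrary W
  W <- matrix(stats::rnorm(6), 2, 3)
  res2 <- structure(list(W = W, means = c(1, -2, 0.5)),
                    class = "unmixing_result")
  out <- separate(X, res2)
  oracle <- matrix(0, nrow(X), 2)
  for (t in seq_len(nrow(X))) {
    xc <- X[t, ] - c(1, -2, 0.5)
    for (k in 1:2) oracle[t, k] <- sum(W[k, ] * xc)
  }
  expect_equal(out, oracle)
  expect_error(separate(X[, 1:2], res2), "channel count")
})

test_that("two mixed non-Gaussian sources are recovered across 20 seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 4000
    S <- cbind(sin(2 * pi * 7 * seq_len(n) / 1000), stats::runif(n, -1, 1))
    A <- matrix(stats::rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(4), 2, 2)
    fit <- suppressWarnings(fit_ica(S %*% t(A), 2, seed = s))
    m <- match_components(fit$components, S)
    min(m$correlation)
  }, numeric(1))
  expect_true(all(hits >= 0.95))
})

test_that("the Amari index is zero exactly for scaled permutations", {
  P <- diag(4)[c(2, 4, 1, 3), ] * c(3, -0.5, 2, 10)   # scaled permutation
  expect_equal(amari_index(P, diag(4)), 0)
  expect_equal(amari_index(diag(4), diag(4)), 0)
  # a uniform (worst-case) product is far from zero
  expect_gt(amari_index(matrix(1, 4, 4), diag(4)), 0.5)
  expect_error(amari_index(matrix(1, 2, 3), diag(3)), "square")
})

test_that("ICA fits are seed-deterministic and report non-convergence", {
  set.seed(99)
  X <- cbind(stats::runif(2000), stats::runif(2000)) %*% matrix(c(1, 2, 3, 4), 2)
  f1 <- suppressWarnings(fit_ica(X, 2, seed = 10))
  f2 <- suppressWarnings(fit_ica(X, 2, seed = 10))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$components, f2$components)
  # an unreachable iteration cap must warn, and the status must say so
  expect_warning(f3 <- fit_ica(X, 2, seed = 1, max_iter = 1, tol = 1e-300),
                 "did not converge")
  expect_false(f3$converged)
})

test_that("components are canonicalized: unit variance, positive peak, variance order", {
  mx <- clean_mixture(31, n = 8000)
  fit <- suppressWarnings(fit_ica(mx$X, 8, seed = 2))
  sds <- apply(fit$components, 2, stats::sd)
  expect_equal(sds, rep(1, 8), tolerance = 1e-6, ignore_attr = TRUE)
  peaks <- apply(fit$components, 2, function(s) s[which.max(abs(s))])
  expect_true(all(peaks > 0))
  expl <- colSums(fit$mixing_estimate^2)
  expect_true(all(diff(expl) <= 1e-8))
})

test_that("high-SNR session sources are recovered from the band-passed stage", {
  # sources with epoch SNR above ~10 at the best electrode (the bilateral
  # frontalis pair under default amplitudes) set the bar: at least that many
  # of the 8 components must match a true source at epoch-correlation >= 0.9.
  # Weak "normal"-amplitude muscles (near the noise floor) are exempt.
  k_high_snr <- 2
  for (sd in c(11, 16)) {
    sess <- simulate_session(protocol_spec(blocks = 1), seed = sd)
    bp <- bandpass(notch(sess$recording))
    fit <- suppressWarnings(fit_ica(bp, 8, seed = 1))
    S <- sapply(sess$sources, `[[`, "samples")
    acts <- vapply(sess$sources, `[[`, character(1), "action")
    ep <- sess$epochs
    cors <- vapply(seq_len(8), function(j) {
      rows <- ep[ep$action == acts[j], ]
      idx <- unlist(lapply(seq_len(nrow(rows)), function(i) {
        rows$onset_sample[i] + seq_len(rows$duration_samples[i]) - 1
      }))
      max(abs(stats::cor(S[idx, j], fit$components[idx, ])))
    }, numeric(1))
    expect_gte(sum(cors >= 0.9), k_high_snr)
  }
})
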