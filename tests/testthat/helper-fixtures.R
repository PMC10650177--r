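# shared fixtures: everything is generated in code at test time

rms <- function(x) sqrt(mean(x^2))

# single-channel sinusoid recording
sine_recording <- function(freq, rate = 1000, dur = 5, amp = 1) {
  t <- seq_len(dur * rate) / rate
  emg_recording(amp * sin(2 * pi * freq * t), rate)
}

# central part of a filtered signal, away from edge transients
core <- function(rec, margin = 1000) {
  n <- n_samples(rec)
  rec$samples[(margin + 1):(n - margin), 1]
}

db <- function(out, inp) 20 * log10(rms(out) / rms(inp))

# compact protocol for fast session tests
tiny_protocol <- function(...) {
  protocol_spec(reps_per_block = 1, blocks = 1, interblock_rest_s = 1,
                cue_duration_s = 0.5, rest_duration_s = 1, ...)
}

# clean continuous 8-source / 16-electrode mixture (no noise), for
# source-recovery checks: independent band-limited Gaussian carriers under
# smooth, source-specific amplitude modulation
clean_mixture <- function(seed, n = 20000) {
  set.seed(seed)
  S <- sapply(1:8, function(j) {
    env <- abs(sin(2 * pi * seq_len(n) / n * (j + 2) + j))
    stats::rnorm(n) * env
  })
  A <- build_mixing_matrix()$matrix
  list(S = S, A = A, X = S %*% t(A))
}

# well-separated 2-D Gaussian blobs
blob_data <- function(n_per = 40, centers = list(c(0, 0), c(6, 6)), sd = 0.3,
                      seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(ctr) {
    cbind(stats::rnorm(n_per, ctr[1], sd), stats::rnorm(n_per, ctr[2], sd))
  }))
  list(x = X, y = rep(letters[seq_along(centers)], each = n_per))
}
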