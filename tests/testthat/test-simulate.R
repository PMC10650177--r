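test_that("activation bursts are confined to their scheduled windows", {
  p <- tiny_protocol()
  act <- generate_activation("frown", "normal", p, rate = 1000, seed = 3)
  sched <- protocol_schedule(p, 1000)
  inside <- rep(FALSE, length(act$samples))
  rows <- sched[sched$action == "frown" & sched$intensity == "normal", ]
  for (i in seq_len(nrow(rows))) {
    inside[rows$onset_sample[i] + seq_len(rows$duration_samples[i]) - 1] <- TRUE
  }
  expect_true(all(act$samples[!inside] == 0))
  expect_gt(rms(act$samples[inside]), 0)
})

test_that("activations are seed-deterministic and validate their labels", {
  p <- tiny_protocol()
  a1 <- generate_activation("frown", "forceful", p, 1000, seed = 7)
  a2 <- generate_activation("frown", "forceful", p, 1000, seed = 7)
  expect_identical(a1$samples, a2$samples)
  expect_error(generate_activation("smirk", "normal", p, 1000, 1), "unknown action")
  expect_error(generate_activation("frown", "gentle", p, 1000, 1), "unknown intensity")
  expect_error(generate_activation("frown", "normal", p, rate = 500, 1), "rate")
})

test_that("zero amplitude gives an all-zero activation", {
  act <- generate_activation("frown", "normal", tiny_protocol(), 1000,
                             seed = 1, amplitude = 0)
  expect_true(all(act$samples == 0))
})

test_that("forceful epochs have about twice the RMS of normal epochs", {
  # Monte-Carlo over 100 seeds; the intensity factor scales the envelope by 2
  p <- tiny_protocol()
  sched <- protocol_schedule(p, 1000)
  win <- function(int) {
    rows <- sched[sched$action == "purse_lips" & sched$intensity == int, ]
    rows$onset_sample[1] + seq_len(rows$duration_samples[1]) - 1
  }
  ratios <- vapply(1:100, function(s) {
    nor <- generate_activation("purse_lips", "normal", p, 1000, seed = s)
    fo <- generate_activation("purse_lips", "forceful", p, 1000, seed = s)
    rms(fo$samples[win("forceful")]) / rms(nor$samples[win("normal")])
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("geometric mixing coefficients follow the inverse-distance law", {
  geom <- list(
    electrodes = tibble::tibble(label = c("e1", "e2"), x = c(1, 2), y = c(0, 0)),
    sources = tibble::tibble(label = c("s1", "s2"), action = c("a", "b"),
                             x = c(0, 0), y = c(0, 0.5))
  )
  # one source at distance d from e1 and 2d from e2 -> coefficient ratio 2:1
  A <- build_mixing_matrix(geom)$matrix
  expect_equal(A["e1", "s1"] / A["e2", "s1"], 2)
  # equidistant sources give equal coefficients in that row
  geom$sources <- tibble::tibble(label = c("s1", "s2"), action = c("a", "b"),
                                 x = c(0, 2), y = c(1, 1))
  A <- build_mixing_matrix(geom)$matrix
  expect_equal(A["e1", "s1"], A["e1", "s2"])
  # coincident positions are rejected
  geom$sources$x[1] <- 1; geom$sources$y[1] <- 0
  expect_error(build_mixing_matrix(geom), "coincident")
})

test_that("the default montage yields a 16 x 8 non-negative mixing matrix", {
  model <- build_mixing_matrix()
  expect_identical(dim(model$matrix), c(16L, 8L))
  expect_true(all(model$matrix >= 0))
  expect_identical(model$electrode_labels[1:2], c("L1", "L2"))
})

test_that("mixing is the linear map the model states", {
  n <- 500
  set.seed(9)
  mk_src <- function(x) structure(list(source_id = "s", action = "a",
                                       intensity = "normal", samples = x,
                                       rate = 1000), class = "source_activation")
  s1 <- mk_src(stats::rnorm(n)); s2 <- mk_src(stats::rnorm(n))
  # identity matrix: channels equal sources
  id <- mixing_model(diag(2))
  out <- mix_sources(list(s1, s2), id)
  expect_equal(out$samples[, 1], s1$samples)
  expect_equal(out$samples[, 2], s2$samples)
  # zero sources map to a zero recording
  z <- mix_sources(list(mk_src(numeric(n)), mk_src(numeric(n))), id)
  expect_true(all(z$samples == 0))
  # known A: brute-force per-sample dot product oracle
  A <- matrix(c(0.3, -1.2, 2, 0.5, 0.1, 7), nrow = 3)
  out <- mix_sources(list(s1, s2), mixing_model(A))
  oracle <- matrix(0, n, 3)
  for (t in seq_len(n)) {
    for (i in 1:3) oracle[t, i] <- A[i, 1] * s1$samples[t] + A[i, 2] * s2$samples[t]
  }
  expect_equal(unname(out$samples), oracle)
  # scalar linearity
  s1b <- mk_src(3 * s1$samples); s2b <- mk_src(3 * s2$samples)
  expect_equal(mix_sources(list(s1b, s2b), mixing_model(A))$samples,
               3 * out$samples)
  # mismatches are rejected
  short <- mk_src(stats::rnorm(n - 1))
  expect_error(mix_sources(list(s1, short), id), "length")
  expect_error(mix_sources(list(s1), id), "count")
})

test_that("interference adds exactly the declared components", {
  rec <- emg_recording(matrix(stats::rnorm(2000), 1000, 2), 1000)
  silent <- noise_spec(powerline_amplitude = 0, dc_offset = 0,
                       white_noise_sd = 0)
  expect_equal(add_interference(rec, silent)$samples, rec$samples)
  # dc only: per-channel mean shifts by exactly c
  dc <- noise_spec(powerline_amplitude = 0, dc_offset = c(0.5, -0.25),
                   white_noise_sd = 0)
  out <- add_interference(rec, dc)
  expect_equal(colMeans(out$samples) - colMeans(rec$samples), c(0.5, -0.25),
               ignore_attr = TRUE)
  # powerline only: difference spectrum peaks at the mains frequency
  pl <- noise_spec(powerline_amplitude = 1e-3, dc_offset = 0,
                   white_noise_sd = 0, powerline_freq = 50)
  diffsig <- add_interference(rec, pl)$samples[, 1] - rec$samples[, 1]
  sp <- power_spectrum(diffsig, 1000)
  expect_equal(sp$freqs[which.max(sp$amplitudes)], 50, tolerance = 1.01)
  expect_error(add_interference(rec, noise_spec(powerline_freq = 600)),
               "Nyquist")
})

test_that("session epochs tile the schedule and match the protocol arithmetic", {
  # default protocol: 3 blocks x 5 reps x 5 actions x 2 intensities
  sched <- protocol_schedule(protocol_spec(), 1000)
  expect_identical(nrow(sched), 150L)
  # a generated compact session: epochs in range, non-overlapping
  p <- tiny_protocol()
  sess <- simulate_session(p, seed = 4)
  ep <- sess$epochs
  expect_identical(nrow(ep), 10L)   # 1 block x 1 rep x 5 actions x 2 intensities
  expect_true(all(ep$onset_sample >= 1))
  expect_true(all(ep$onset_sample + ep$duration_samples - 1 <=
                    n_samples(sess$recording)))
  ends <- ep$onset_sample + ep$duration_samples - 1
  expect_true(all(ep$onset_sample[-1] > ends[-nrow(ep)]))
  expect_identical(ep$duration_samples, rep(2000L, 10L))
})

test_that("a one-trial protocol yields exactly one epoch of the action length", {
  p <- protocol_spec(actions = "frown", intensities = "forceful",
                     reps_per_block = 1, blocks = 1, cue_duration_s = 0.5,
                     rest_duration_s = 1, interblock_rest_s = 1)
  sess <- simulate_session(p, seed = 2)
  expect_identical(nrow(sess$epochs), 1L)
  expect_identical(sess$epochs$duration_samples, 2000L)
})

test_that("sessions are bit-reproducible under the same seed", {
  p <- tiny_protocol()
  s1 <- simulate_session(p, seed = 5)
  s2 <- simulate_session(p, seed = 5)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$epochs, s2$epochs)
  s3 <- simulate_session(p, seed = 6)
  expect_false(identical(s1$recording$samples, s3$recording$samples))
})

test_that("label tables round-trip through TSV", {
  sess <- simulate_session(tiny_protocol(), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(sess$epochs, path)
  back <- read_labels(path)
  expect_equal(back$action, sess$epochs$action)
  expect_equal(back$onset_sample, sess$epochs$onset_sample)
})
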