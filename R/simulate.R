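#' Session protocol specification
#'
#' The cued acquisition protocol: five facial actions at two intensities,
#' repeated `reps_per_block` times per block over `blocks` blocks. Each trial
#' is a 2 s picture cue, a 2 s action window and a 3 s rest, run sequentially;
#' blocks are separated by a 30 s rest. The defaults give
#' 3 x 5 x 5 x 2 = 150 labeled action epochs per session.
#'
#' @param actions Ordered character vector of action labels.
#' @param intensities Ordered character vector of intensity labels.
#' @param reps_per_block Repetitions of the action set per block.
#' @param blocks Number of blocks.
#' @param action_duration_s,rest_duration_s,interblock_rest_s,cue_duration_s
#'   Phase durations in seconds (all > 0; `interblock_rest_s` and
#'   `cue_duration_s` may be 0 for compact test protocols).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(actions = facial_actions(),
                          intensities = c("normal", "forceful"),
                          reps_per_block = 5L, blocks = 3L,
                          action_duration_s = 2, rest_duration_s = 3,
                          interblock_rest_s = 30, cue_duration_s = 2) {
  stopifnot(length(actions) >= 1L, length(intensities) >= 1L,
            reps_per_block >= 1L, blocks >= 1L,
            action_duration_s > 0, rest_duration_s > 0,
            interblock_rest_s >= 0, cue_duration_s >= 0)
  structure(list(actions = actions, intensities = intensities,
                 reps_per_block = as.integer(reps_per_block),
                 blocks = as.integer(blocks),
                 action_duration_s = action_duration_s,
                 rest_duration_s = rest_duration_s,
                 interblock_rest_s = interblock_rest_s,
                 cue_duration_s = cue_duration_s),
            class = "protocol_spec")
}

#' Facial action vocabulary
#' @return The five action labels in protocol order.
#' @export
facial_actions <- function() {
  c("raise_eyebrows", "frown", "close_eyes", "purse_lips", "lift_mouth_corners")
}

#' Interference specification
#'
#' Additive contamination applied to a clean mixed recording: a per-channel DC
#' offset, a common-phase powerline sinusoid, and broadband white noise.
#' Defaults model a 50 Hz mains environment and a few microvolts of amplifier
#' noise.
#'
#' @param powerline_freq Mains frequency in Hz.
#' @param powerline_amplitude Sinusoid amplitude in volts (>= 0).
#' @param dc_offset Per-channel DC offset in volts (recycled across channels).
#' @param white_noise_sd Standard deviation of the broadband noise in volts.
#' @param seed Integer seed; the same seed reproduces the session bit for bit.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(powerline_freq = 50, powerline_amplitude = 10e-6,
                       dc_offset = 1e-3, white_noise_sd = 3e-6, seed = 1L) {
  stopifnot(powerline_freq > 0, powerline_amplitude >= 0,
            white_noise_sd >= 0)
  structure(list(powerline_freq = powerline_freq,
                 powerline_amplitude = powerline_amplitude,
                 dc_offset = dc_offset, white_noise_sd = white_noise_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default perifacial geometry
#'
#' A 2-D sketch of the distal electrode montage: 16 electrodes (`L1..L8`,
#' `R1..R8`) evenly spaced on a face-shaped ellipse (half-axes 9 x 12 cm), and
#' 8 muscle sources placed at the approximate positions of the bilateral
#' frontalis, orbicularis oculi and zygomaticus plus the midline corrugator
#' and orbicularis oris. Each source is tagged with the facial action that
#' recruits it.
#'
#' @return A list with tibbles `electrodes` (label, x, y) and `sources`
#'   (label, action, x, y); coordinates in cm.
#' @export
facial_geometry <- function() {
  ang <- (seq_len(16) - 0.5) * 2 * pi / 16
  ex <- 9 * cos(ang); ey <- 12 * sin(ang)
  side <- ifelse(ex < 0, "L", "R")
  idx <- stats::ave(seq_along(side), side, FUN = seq_along)
  electrodes <- tibble::tibble(label = paste0(side, idx), x = ex, y = ey)
  # order L1..L8 then R1..R8 (the device's channel order)
  electrodes <- electrodes[order(substr(electrodes$label, 1, 1),
                                 as.integer(substring(electrodes$label, 2))), ]
  sources <- tibble::tibble(
    label = c("frontalis_l", "frontalis_r", "corrugator",
              "orb_oculi_l", "orb_oculi_r", "orb_oris",
              "zygomaticus_l", "zygomaticus_r"),
    action = c("raise_eyebrows", "raise_eyebrows", "frown",
               "close_eyes", "close_eyes", "purse_lips",
               "lift_mouth_corners", "lift_mouth_corners"),
    x = c(-3, 3, 0, -4, 4, 0, -4.5, 4.5),
    y = c(8, 8, 7, 5, 5, -5, -2, -2)
  )
  list(electrodes = electrodes, sources = sources)
}

#' Volume-conduction mixing matrix
#'
#' Builds the electrode x source mixing matrix from 2-D geometry under a
#' distance-attenuation law. The default inverse-distance law sets
#' `A[i, j] = 1 / d(i, j)^exponent` (distances in cm), so coefficients fall
#' monotonically with distance and an electrode twice as far from a source
#' receives half the coefficient (exponent 1).
#'
#' @param geometry As returned by [facial_geometry()].
#' @param attenuation_law Only `"inverse_distance"` is provided.
#' @param exponent Positive attenuation exponent (default 1).
#' @return An object of class `mixing_model`: `electrode_labels`,
#'   `source_labels`, `matrix` (n_electrodes x n_sources), `geometry`.
#' @export
build_mixing_matrix <- function(geometry = facial_geometry(),
                                attenuation_law = "inverse_distance",
                                exponent = 1) {
  attenuation_law <- match.arg(attenuation_law, "inverse_distance")
  stopifnot(exponent > 0)
  el <- geometry$electrodes; so <- geometry$sources
  d <- outer(seq_len(nrow(el)), seq_len(nrow(so)), function(i, j) {
    sqrt((el$x[i] - so$x[j])^2 + (el$y[i] - so$y[j])^2)
  })
  if (any(d == 0)) stop("coincident electrode and source positions")
  A <- 1 / d^exponent
  dimnames(A) <- list(el$label, so$label)
  structure(list(electrode_labels = el$label, source_labels = so$label,
                 matrix = A, geometry = geometry),
            class = "mixing_model")
}

#' Construct a mixing model from an explicit matrix
#'
#' @param matrix n_electrodes x n_sources numeric matrix.
#' @param electrode_labels,source_labels Optional label vectors.
#' @return A `mixing_model`.
#' @export
mixing_model <- function(matrix, electrode_labels = NULL, source_labels = NULL) {
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("mixing matrix must be finite")
  if (is.null(electrode_labels)) electrode_labels <- default_channel_labels(nrow(matrix))
  if (is.null(source_labels)) source_labels <- paste0("s", seq_len(ncol(matrix)))
  dimnames(matrix) <- list(electrode_labels, source_labels)
  structure(list(electrode_labels = electrode_labels,
                 source_labels = source_labels, matrix = matrix,
                 geometry = NULL),
            class = "mixing_model")
}

# default per-action envelope peak amplitudes at the source, in volts.
# close_eyes and frown are deliberately weak so that their "normal" epochs sit
# near the simulated noise floor, mimicking the hard-to-capture actions of a
# distal montage.
default_action_amplitudes <- function() {
  c(raise_eyebrows = 100e-6, frown = 30e-6, close_eyes = 25e-6,
    purse_lips = 120e-6, lift_mouth_corners = 90e-6)
}

default_intensity_factors <- function(forceful_factor = 2) {
  c(normal = 1, forceful = forceful_factor)
}

#' Trial schedule of a protocol
#'
#' Expands a [protocol_spec()] into per-trial action windows at a given
#' sampling rate. Phases within a trial run sequentially: cue, action, rest.
#'
#' @param protocol A [protocol_spec()].
#' @param rate Sampling rate in Hz.
#' @return A tibble with one row per action epoch: `epoch_id`, `block`, `rep`,
#'   `action`, `intensity`, `onset_sample` (1-based), `duration_samples`; the
#'   total session length in samples is attached as attribute `total_samples`.
#' @export
protocol_schedule <- function(protocol, rate) {
  trial_len <- as.integer(round((protocol$cue_duration_s + protocol$action_duration_s +
                                   protocol$rest_duration_s) * rate))
  act_len <- as.integer(round(protocol$action_duration_s * rate))
  cue_len <- as.integer(round(protocol$cue_duration_s * rate))
  inter <- as.integer(round(protocol$interblock_rest_s * rate))
  grid <- tidyr::expand_grid(
    block = seq_len(protocol$blocks),
    rep = seq_len(protocol$reps_per_block),
    action = protocol$actions,
    intensity = protocol$intensities
  )
  trials_per_block <- protocol$reps_per_block * length(protocol$actions) *
    length(protocol$intensities)
  trial_in_block <- (seq_len(nrow(grid)) - 1L) %% trials_per_block
  block0 <- grid$block - 1L
  block_start <- block0 * (trials_per_block * trial_len + inter)
  onset <- block_start + trial_in_block * trial_len + cue_len + 1L
  out <- tibble::tibble(
    epoch_id = seq_len(nrow(grid)),
    block = grid$block, rep = grid$rep,
    action = grid$action, intensity = grid$intensity,
    onset_sample = onset, duration_samples = act_len
  )
  attr(out, "total_samples") <- protocol$blocks * trials_per_block * trial_len +
    (protocol$blocks - 1L) * inter
  out
}

# raised-cosine (Tukey) burst envelope, taper fraction of each end
raised_cosine_envelope <- function(n, taper = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  env <- rep(1, n)
  a <- taper
  lo <- t < a
  hi <- t > 1 - a
  env[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
  env[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a) / a)))
  env
}

# band-limit white noise to the sEMG band (20-350 Hz) and rescale to unit RMS
shaped_carrier <- function(n, rate) {
  x <- stats::rnorm(n)
  nyq <- rate / 2
  hi <- min(350, 0.9 * nyq)
  if (n > 24 && hi > 20) {
    bf <- signal::butter(4, c(20, hi) / nyq, type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

#' Generate one source activation
#'
#' The source signal of a single muscle for a whole session: band-limited
#' (20-350 Hz shaped) Gaussian noise multiplied by a raised-cosine burst
#' envelope inside every scheduled window of the given action and intensity,
#' exactly zero elsewhere. Forceful trials scale the envelope by
#' `forceful_factor`.
#'
#' @param action,intensity Labels drawn from the protocol vocabulary.
#' @param protocol A [protocol_spec()].
#' @param rate Sampling rate in Hz (must be at least twice the 350 Hz source
#'   bandwidth).
#' @param seed Integer seed; same arguments and seed give identical samples.
#' @param amplitude Envelope peak amplitude in volts; defaults to the
#'   per-action table of the simulator.
#' @param forceful_factor Envelope scale of forceful relative to normal.
#' @param trial_jitter_sd Lognormal sd (log scale) of the per-trial amplitude;
#'   0 disables inter-trial variability.
#' @param onset_jitter_s Maximum uniform delay of the burst onset within its
#'   window, in seconds (the burst never leaves the scheduled window).
#' @return An object of class `source_activation`: `source_id`, `action`,
#'   `intensity`, `samples` (length = full session), `rate`.
#' @export
generate_activation <- function(action, intensity, protocol, rate, seed,
                                amplitude = NULL, forceful_factor = 2,
                                trial_jitter_sd = 0.2, onset_jitter_s = 0.1) {
  if (!action %in% protocol$actions) stop("unknown action label: ", action)
  if (!intensity %in% protocol$intensities) {
    stop("unknown intensity label: ", intensity)
  }
  if (rate < 700) stop("`rate` must be at least twice the 350 Hz source bandwidth")
  if (is.null(amplitude)) {
    amps <- default_action_amplitudes()
    amplitude <- if (action %in% names(amps)) amps[[action]] else 100e-6
  }
  scale <- amplitude * default_intensity_factors(forceful_factor)[[intensity]]
  sched <- protocol_schedule(protocol, rate)
  total <- attr(sched, "total_samples")
  x <- numeric(total)
  rows <- sched[sched$action == action & sched$intensity == intensity, ]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, match(action, protocol$actions) * 7L +
                         match(intensity, protocol$intensities)))
  for (i in seq_len(nrow(rows))) {
    n <- rows$duration_samples[i]
    trial_amp <- scale *
      if (trial_jitter_sd > 0) exp(stats::rnorm(1, 0, trial_jitter_sd)) else 1
    shift <- if (onset_jitter_s > 0) {
      sample.int(max(1L, round(onset_jitter_s * rate)), 1L) - 1L
    } else 0L
    nb <- n - shift
    idx <- rows$onset_sample[i] + shift + seq_len(nb) - 1L
    x[idx] <- trial_amp * raised_cosine_envelope(nb) * shaped_carrier(nb, rate)
  }
  structure(list(source_id = paste0(action, "_", intensity), action = action,
                 intensity = intensity, samples = x, rate = rate),
            class = "source_activation")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mix source activations onto the electrode array
#'
#' Linear instantaneous mixing: electrode channel `i` at time `t` is
#' `sum_j A[i, j] * s_j(t)`.
#'
#' @param sources List of [generate_activation()] results (or any objects with
#'   `samples` and `rate`), in the order of `model$source_labels`.
#' @param model A `mixing_model`.
#' @return An [emg_recording()] with one channel per electrode.
#' @export
mix_sources <- function(sources, model) {
  stopifnot(inherits(model, "mixing_model"))
  if (length(sources) != length(model$source_labels)) {
    stop("source count does not match the mixing model (",
         length(sources), " vs ", length(model$source_labels), ")")
  }
  rates <- vapply(sources, `[[`, numeric(1), "rate")
  lens <- vapply(sources, function(s) length(s$samples), integer(1))
  if (length(unique(rates)) != 1L) stop("sources disagree on sampling rate")
  if (length(unique(lens)) != 1L) stop("sources disagree on length")
  S <- vapply(sources, `[[`, numeric(lens[1]), "samples")  # time x n_sources
  X <- S %*% t(model$matrix)                               # time x n_electrodes
  emg_recording(X, rates[1], model$electrode_labels)
}

#' Add interference to a recording
#'
#' Adds, per channel, a DC offset, a common-phase powerline sinusoid and
#' white Gaussian noise. Seeded through `noise$seed`; zero-amplitude
#' components leave the recording untouched.
#'
#' @param recording An [emg_recording()].
#' @param noise A [noise_spec()]; `powerline_freq` must be below Nyquist.
#' @return A contaminated [emg_recording()].
#' @export
add_interference <- function(recording, noise) {
  stopifnot(inherits(recording, "emg_recording"), inherits(noise, "noise_spec"))
  if (noise$powerline_freq >= recording$rate / 2) {
    stop("powerline frequency at or above Nyquist")
  }
  n <- n_samples(recording); k <- n_channels(recording)
  t <- (seq_len(n) - 1) / recording$rate
  pl <- noise$powerline_amplitude * sin(2 * pi * noise$powerline_freq * t)
  dc <- rep_len(noise$dc_offset, k)
  out <- recording$samples + pl
  out <- sweep(out, 2L, dc, `+`)
  if (noise$white_noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(derive_seed(noise$seed, 9999L))
    out <- out + matrix(stats::rnorm(n * k, sd = noise$white_noise_sd), n, k)
  }
  emg_recording(out, recording$rate, recording$channel_labels, recording$adc)
}

#' Simulate a full cued session
#'
#' Generates all muscle-source activations for the protocol, mixes them
#' through the volume-conduction model and adds interference. Each muscle
#' source responds to its assigned action at both intensities.
#'
#' @param protocol A [protocol_spec()].
#' @param model A `mixing_model` whose geometry carries per-source action
#'   assignments (see [facial_geometry()]).
#' @param noise A [noise_spec()].
#' @param rate Sampling rate in Hz.
#' @param seed Integer session seed; fans out deterministically to sources and
#'   noise.
#' @return A list with `recording` (an [emg_recording()]), `epochs` (labeled
#'   epoch tibble: `epoch_id`, `block`, `rep`, `action`, `intensity`,
#'   `onset_sample`, `duration_samples`) and `sources` (the activations).
#' @export
simulate_session <- function(protocol = protocol_spec(),
                             model = build_mixing_matrix(),
                             noise = noise_spec(), rate = 1000, seed = 1L) {
  if (is.null(model$geometry)) {
    stop("simulate_session() needs a geometry-derived model with source actions")
  }
  src_tab <- model$geometry$sources
  sched <- protocol_schedule(protocol, rate)
  total <- attr(sched, "total_samples")
  sources <- vector("list", nrow(src_tab))
  for (j in seq_len(nrow(src_tab))) {
    # muscles whose action the protocol never cues stay silent
    if (!src_tab$action[j] %in% protocol$actions) {
      tot <- numeric(total)
    } else {
      per_int <- lapply(protocol$intensities, function(int) {
        generate_activation(src_tab$action[j], int, protocol, rate,
                            seed = derive_seed(seed, 101L * j))
      })
      tot <- Reduce(`+`, lapply(per_int, `[[`, "samples"))
    }
    sources[[j]] <- structure(
      list(source_id = src_tab$label[j], action = src_tab$action[j],
           intensity = "both", samples = tot, rate = rate),
      class = "source_activation"
    )
  }
  clean <- mix_sources(sources, model)
  noise$seed <- derive_seed(seed, 5000L)
  rec <- add_interference(clean, noise)
  epochs <- protocol_schedule(protocol, rate)
  attr(epochs, "total_samples") <- NULL
  list(recording = rec, epochs = epochs, sources = sources)
}

#' Extract the labeled epochs of a recording as a list of segments
#'
#' @param recording An [emg_recording()] (or a plain matrix of component
#'   signals, time x components).
#' @param epochs Epoch tibble from [simulate_session()] / [read_labels()].
#' @return A list of time x channel matrices, one per epoch row.
#' @export
epoch_segments <- function(recording, epochs) {
  mat <- if (inherits(recording, "emg_recording")) recording$samples else as.matrix(recording)
  lapply(seq_len(nrow(epochs)), function(i) {
    idx <- epochs$onset_sample[i] + seq_len(epochs$duration_samples[i]) - 1L
    if (max(idx) > nrow(mat)) stop("epoch ", i, " extends past the recording")
    mat[idx, , drop = FALSE]
  })
}

#' Read and write epoch label tables
#'
#' Tab-separated with columns `epoch_id`, `action`, `intensity`,
#' `onset_sample`, `duration_samples` (extra columns preserved).
#'
#' @param epochs Epoch tibble.
#' @param path File path.
#' @return `read_labels()` returns a tibble; `write_labels()` its path,
#'   invisibly.
#' @export
write_labels <- function(epochs, path) {
  utils::write.table(epochs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
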