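---
title: "Perifacial sEMG analysis with perifemg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perifacial sEMG analysis with perifemg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perifemg)
```

## The measurement problem

Facial-muscle movements can be read from surface electromyography (sEMG)
without placing electrodes on the muscles themselves. A *distal* (perifacial)
montage rings the face with 16 electrodes (`L1..L8`, `R1..R8`) and records the
crosstalk that every contracting muscle volume-conducts to the face's
periphery. Each electrode therefore sees a *mixture* of several muscle
sources; the analysis stack has to (1) condition the raw signals, (2) undo the
mixing by blind source separation, (3) summarize each separated component by a
small feature set per cued epoch, and (4) classify which of five facial
actions — raising the eyebrows, frowning, closing the eyes, pursing the lips,
lifting the mouth corners — produced the epoch, at either of two intensities
(normal / forceful).

perifemg implements this stack end to end, together with the device-side data
model of the 24-bit acquisition hardware (code/voltage conversion, frame
packetization, throughput arithmetic, a plain-text recording dialect) and the
statistics used to compare two acquisition devices channel against channel.
Because no human recordings ship with the package, a volume-conduction
simulator generates sessions with the statistical structure the pipeline
assumes; everything downstream is tested against it.

## The generative model of the simulator

**Sources.** Each of 8 muscle sources (bilateral frontalis, orbicularis
oculi and zygomaticus, midline corrugator and orbicularis oris) emits
band-limited (20–350 Hz shaped) Gaussian noise multiplied by a raised-cosine
burst envelope inside every scheduled window of its action, and is exactly
zero elsewhere. Forceful trials scale the envelope by 2. The 20–350 Hz
shaping matches the energy band the conditioning chain preserves, and an
amplitude-modulated Gaussian process is the standard stochastic model for
constant-force sEMG.

Two forms of inter-trial variability are built in, with defaults chosen to be
realistic rather than convenient:

* per-trial amplitude jitter, lognormal with sd 0.2 on the log scale
  (≈ 20 % coefficient of variation), and
* a uniform onset delay of up to 0.1 s within the scheduled window
  (reaction-time variability; the burst never leaves its window).

These are not cosmetic. If the two sources of a bilateral pair fired with
*identical* deterministic envelopes, their joint distribution within a burst
would be a spherically symmetric scale mixture of Gaussians — a configuration
that independent component analysis provably cannot orient (any rotation of
the pair has the same distribution). Real bilateral activations are not
perfectly symmetric, and the jitter restores identifiability for exactly the
reason asymmetry does in vivo.

**Per-action amplitudes.** Envelope peaks default to 100 µV (raise eyebrows),
120 µV (purse lips), 90 µV (lift mouth corners), 30 µV (frown) and 25 µV
(close eyes) at the source. The last two are deliberately near the simulated
noise floor: in distal recordings, normal-intensity eye closure and frowning
are the actions a perifacial montage can barely capture, and the simulator
mirrors that phenomenology. All amplitudes are configurable.

**Mixing.** Electrode coefficients follow an inverse-distance law
`A[i, j] = 1 / d(i, j)^p` (default exponent 1) on a 2-D sketch of the montage:
16 electrodes on a 9 × 12 cm ellipse, sources at approximate muscle positions.
Volume conduction is only characterized qualitatively in the literature for
this montage; inverse distance is the simplest monotone law and the exponent
is exposed. The matrix is 16 × 8: the mixing equation is conventionally
written square, but the pipeline maps 16 electrodes to 8 components, so the
rectangular generalization (PCA whitening followed by a square 8 × 8 rotation)
is used throughout.

**Protocol.** The cued session is 3 blocks × 5 repetitions × 5 actions × 2
intensities = 150 labeled epochs. Each trial is a 2 s picture cue, a 2 s
action window and a 3 s rest, run sequentially; blocks are separated by 30 s.
The cue/display overlap is ambiguous in the underlying protocol description;
phases are treated as strictly sequential here, without asserting that this
was the original intent.

**Interference.** A per-channel DC offset (default 1 mV), a common-phase
50 Hz powerline sinusoid (default 10 µV) and white Gaussian noise (default
3 µV sd) are added after mixing. 50 Hz reflects a mains-is-50-Hz locale.
Everything is seeded; the same seed reproduces a session bit for bit.

**What the simulator does not emulate.** Motor-unit action potentials and
firing statistics, electrode-skin impedance drift, motion artifacts,
inter-subject anatomy, cross-talk nonlinearity, and label noise from manual
video annotation. Tests passing on simulated sessions therefore demonstrate
the *pipeline's* correctness under its stated assumptions — linear
instantaneous mixing, stationary noise, scheduled bursts — not field
performance on human data. In particular the classification accuracies
reached on clean synthetic sessions (§ Benchmarks) are upper bounds, not
predictions.

## The conditioning chain

Stages run in this order, each per channel, zero-phase
(forward–backward) by default so epoch alignment is preserved:

1. **Notch** at 50 Hz, constrained biquad, quality 30 (bandwidth
   `f0/Q ≈ 1.7 Hz`). The designed single-pass response is ≥ 30 dB down at the
   notch and within 1 dB at ±10 Hz; zero-phase application doubles the dB
   numbers, and the tests account for that.
2. **Band-pass** 20–350 Hz Butterworth, "fourth order" in the Matlab
   convention (`butter(4, c(20, 350)/nyq)`, an order-8 recursive filter with
   −3 dB at each corner in single-pass mode). A 5 Hz tone is attenuated by
   ≈ 48 dB in single-pass mode, ≈ double that zero-phase.
3. **DC removal** (mean subtraction). The band-pass already suppresses DC;
   the stage is kept because the reference processing chain lists it
   explicitly after the band-pass, and it is idempotent and cheap.
4. **Full-wave rectification** (absolute value).
5. **Linear envelope**: 2nd-order Butterworth low-pass, default cutoff
   10 Hz. A recursive low-pass can undershoot slightly, so small negative
   envelope values are possible and are deliberately not clipped.

The chain's defaults (notch frequency and quality, envelope order and
cutoff, zero-phase mode) are design choices of this package; the reference
description names the stages and the band corners but none of these numbers.

**What ICA consumes.** The reference chain is ambiguous about whether source
separation runs on the envelope (the chain's final output) or on the
band-passed signal. `run_pipeline()` defaults to the full chain output and
exposes `filters$ica_input = "bandpass"` as the alternative. The distinction
matters for a reason worth documenting: envelopes of bilateral sources that
share a schedule are strongly correlated by construction (both are smooth
non-negative bursts in the same windows), so envelope-domain ICA cannot fully
separate such pairs even in principle; band-passed signals keep the
independent carriers and separate cleanly. The package's source-recovery
tests run on the band-passed stage for exactly this reason, while the
feature/classification path keeps the reference default.

## Source separation

`fit_ica()` is a fixed-point iteration with the log-cosh contrast and
symmetric decorrelation after PCA whitening to `n_components` (default 8).
Numerical choices:

* tolerance 1e-5 on the rotation update and up to 400 iterations. A looser
  1e-4 criterion — common as a library default — was observed to fire
  prematurely on burst-structured signals, whose fixed-point surface is
  shallow; the tighter setting costs little and stops the iteration only
  when the rotation is actually stationary.
* 3 restarts from independent random orthogonal initializations, keeping the
  run whose components deviate most from Gaussianity (summed squared
  deviation of `E[log cosh u]` from the Gaussian baseline 0.3746). Single
  runs occasionally settle in a rotated local optimum within a
  bilateral-pair subspace; restarts make the fit robust without changing the
  estimator.
* Non-convergence raises a *warning*, never silently: for purely Gaussian
  sources the model is unidentifiable and failure to converge is the
  expected, reported outcome.

Components are canonicalized — unit variance, sign fixed so the
largest-magnitude sample is positive, ordered by explained input variance —
because ICA is only defined up to sign, scale and permutation. All recovery
tests use ambiguity-invariant matching (greedy assignment by absolute
correlation) and the Amari index, which is permutation- and scale-invariant
by construction. Recovery of session sources is measured on epoch-restricted
correlation (within the source's scheduled windows): outside its bursts a
source is identically zero, so whole-session correlation is bounded by the
≈ 2 % duty cycle of the protocol no matter how good the separation is.

`W` is estimated per recording session; nothing in the reference setup
defines a cross-subject scheme, and per-session fitting is the conservative
default.

## Features

Eight features per component per epoch, computed on the whole 2 s epoch with
no sub-windowing, giving the 64-dimensional vector (8 components × 8
features) used for classification:

| feature | definition | note |
|---|---|---|
| IEMG | `sum(|x|)` | = N·MAV exactly |
| VAR | `mean((x - mean(x))^2)` | population 1/N form, not 1/(N−1) |
| MAV | `mean(|x|)` | |
| SSI | `sum(x^2)` | = N·RMS² exactly |
| RMS | `sqrt(mean(x^2))` | |
| FC | `sum(f·S)/sum(S)` | spectral centroid, Hz |
| MF | `sum(S)/N` | **mean spectral amplitude** |
| FRMS | `sqrt(sum(f²·S)/sum(S))` | ≥ FC by Cauchy–Schwarz |

Two definitions deserve emphasis. *MF here is the mean of the spectrum
amplitudes* — exactly as defined in the feature table this package follows —
even though "MF" elsewhere usually denotes the median frequency; its units
are spectrum-amplitude units, not Hz. And `N` in MF is the number of spectrum
bins, the only reading under which the formula is well-defined on a spectrum.

The spectrum estimator `S(n)` is unspecified in the reference feature table;
the package uses the magnitude spectrum of the mean-detrended epoch from a
single discrete Fourier transform (amplitude convention `2|X|/N`), with the
estimator name recorded in the result. An all-zero epoch has no defined FC
or FRMS; the package raises an explicit error rather than emitting silent
zeros, so a feature matrix can never quietly contain placeholder values.

## Agreement statistics

For two aligned signals (e.g. the same movement captured by two devices):
Spearman rank correlation (average ranks on ties), signal energy
`sum(x²)·dt` with the two-signal ratio reported as `min/max` so it is
symmetric and lands in [0, 1], the centered linear correlation coefficient,
and the lag-0 normalized cross-correlation — which is algebraically the same
quantity as the LCC and is verified to agree to 1e-12; an optional max-lag
mode scans integer shifts and reports the best lag. Signals are aligned by
epoch onset; no time warping is applied.

## Classifiers

All three operate on the standardized 64-dimensional feature vectors
(standardization learned on the training split only):

* **One-vs-rest Gaussian-kernel SVM.** One binary soft-margin subproblem per
  class (that class positive, rest negative), solved in the dual by libsvm
  via e1071; the *decision function is evaluated by this package's own
  code* from the stored dual coefficients,
  `f_m(x) = Σ α_i^m y_i K(x, x_i) + b_m`, prediction takes the maximal
  `f_m`. A KKT audit (`kkt_audit()`) checks `0 ≤ α ≤ C` and `Σ α y = 0` per
  subproblem. Defaults `C = 1` and kernel width `1/(n_features · mean
  feature variance)`.
* **Random forest**, 200 trees, with the package's own majority vote over
  per-tree votes; an exact tie is broken deterministically in favor of the
  lowest class index.
* **BPNN**: a plain multilayer feedforward network (one hidden layer of 32
  tanh units by default, softmax output) trained by full-batch gradient
  descent on the cross-entropy loss — forward propagation then
  backpropagation, the textbook algorithm — with the per-epoch loss stored.
  200 epochs and learning rate 0.1 by default; the benchmark uses 400
  epochs. It is intentionally the simplest member of the trio.

Recall and F1 are macro-averaged (equal class weight) and every report tags
its averaging scheme; the reference evaluation does not state its averaging.
The train/test split is 80/20, random, stratified by default (a flag
disables stratification); when a class is so small that the rounded train
share would swallow it, one sample is always held out so every class appears
on both sides. Splits, forests, networks and ICA restarts all derive their
randomness from explicit seeds; a single pipeline seed fans out to per-stage
seeds through a fixed affine map, so any stage can be reproduced in
isolation.

## Benchmarks and problem sizes

`run_benchmark()` runs the five-class task (forceful epochs only, action
labels CE/PL/RE/LCM/FR) and the ten-class task (all epochs, action ×
intensity labels like `CE_N`). On default synthetic sessions the random
forest reaches perfect or near-perfect five-class accuracy — unsurprising,
since the simulator's assumptions are exactly the pipeline's assumptions and
the default noise floor is low. The test suite asserts only that the forest
reaches ≥ 0.8 and is not outperformed by the BPNN; the full ranking across
classifiers is reported rather than asserted, since on human recordings it
depends on data properties the simulator does not emulate.

The suite and the acceptance script size their simulations to run on one
CPU in minutes: compact protocols (1 block, 1–3 repetitions, shortened
rests) for layout and property checks, 20 × 20 000-sample clean mixtures for
source-recovery statistics, and one full 1110 s default session for the
end-to-end benchmark. These sizes are the package's own choices and are
stated here so results can be regenerated exactly.

## Known limitations

* The simulator's linear instantaneous mixing ignores propagation delay and
  tissue filtering; ICA inherits those assumptions.
* Envelope-domain ICA cannot fully separate co-scheduled bilateral pairs
  (see above); the package documents rather than hides this.
* The BPNN is full-batch gradient descent without momentum or adaptive
  rates; it is a reference implementation, not a competitive one.
* Device frame layout (header `0xA5 0x5A`, little-endian packet number,
  XOR checksum) is this package's documented dialect: the hardware
  description names the fields but not the byte layout, so round-tripping
  real device captures may require adapting `encode_frame()`/
  `decode_frame()`.
* `vref = 4.5 V` and the LSB law `vref/(gain · (2^23 − 1))` are the
  conventional values for this ADC family, not measured ones; both are
  configurable in `adc_config()`.
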