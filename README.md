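# perifemg

Analysis toolkit for **perifacial surface electromyography (sEMG)**:
recognizing facial-muscle movements from a *distal* electrode montage, where
16 electrodes (`L1..L8`, `R1..R8`) around the periphery of the face record
volume-conducted crosstalk from the muscle sources instead of sitting on top
of them. Every electrode sees a linear mixture of several muscles, so the
pipeline is:

```
simulate/acquire → condition → unmix (ICA) → extract features → classify
```

* **Device data model** — 24-bit delta-sigma ADC code↔voltage conversion
  (`volts = code · vref / (gain · (2²³ − 1))`, gain 24), frame
  packetization with checksum and dropped-packet detection, throughput
  arithmetic `D = N · fs · R` (16 channels × 1 kHz × 32 bit = 512 Kb/s), and
  a plain-text recording dialect.
* **Conditioning chain** — 50 Hz notch, 20–350 Hz 4th-order Butterworth
  band-pass, DC removal, full-wave rectification, 10 Hz linear envelope;
  zero-phase by default.
* **Blind source separation** — fixed-point ICA (log-cosh contrast,
  symmetric decorrelation, restarts) after PCA whitening from 16 channels to
  8 components, `s(t) = W x(t)`.
* **Features** — the eight classic per-component features per 2 s epoch
  (IEMG, VAR, MAV, SSI, RMS; spectral centroid FC, mean spectral amplitude
  MF, root-mean-square frequency FRMS), 8 × 8 = 64 features per epoch.
* **Classification** — one-vs-rest Gaussian-kernel SVM
  (`f_m(x) = Σ αᵢᵐ yᵢ K(x, xᵢ) + b_m`, with a KKT feasibility audit of the
  dual), random forest with explicit majority voting, and a
  backpropagation neural network; accuracy / macro-recall / macro-F1 with
  confusion matrices for the five-class (forceful) and ten-class
  (action × intensity) tasks.
* **Device agreement** — Spearman, min/max energy ratio, linear correlation
  and lag-0 (or max-lag) cross-correlation, reported per movement.
* **Simulator** — since no human recordings are distributed, a seeded
  volume-conduction simulator generates full cued sessions
  (3 blocks × 5 reps × 5 actions × 2 intensities = 150 labeled epochs;
  burst-modulated Gaussian sources, inverse-distance mixing over a 2-D face
  sketch, powerline/DC/white-noise interference) against which the entire
  stack is tested.

Everything is tidyverse-friendly: feature matrices, reports and label
tables are tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` visualizations.

## Worked example

Simulate a one-block session, condition it, unmix, extract the 64-dim
feature matrix, and benchmark the classifiers:

```r
library(perifemg)

sess <- simulate_session(protocol_spec(blocks = 1), seed = 42)
sess$recording
#> <emg_recording> 16 channel(s) x 350000 samples @ 1000 Hz (350.000 s)
#> channels: L1, L2, L3, L4, L5, L6, L7, L8 ...

clean <- preprocess_chain(sess$recording)
fit <- fit_ica(bandpass(notch(sess$recording)), n_components = 8, seed = 42)
fit
#> <unmixing_result> 8 components, converged after 55 iteration(s)

fm <- extract_feature_matrix(separate(clean, fit), sess$epochs, rate = 1000)
fm[1:4, c("action", "intensity", "c1_rms", "c1_fc", "c1_mf")]
#> # A tibble: 4 × 5
#>   action         intensity c1_rms c1_fc    c1_mf
#>   <chr>          <chr>      <dbl> <dbl>    <dbl>
#> 1 raise_eyebrows normal     1.63   4.32 0.00277
#> 2 raise_eyebrows forceful   3.53   4.90 0.00619
#> 3 frown          normal     0.199 18.3  0.000362
#> 4 frown          forceful   0.517  9.16 0.000874

res <- run_benchmark(fm, task = "five_class", seed = 42)
res[, c("classifier", "accuracy", "recall", "f1")]
#> # A tibble: 3 × 4
#>   classifier accuracy recall    f1
#>   <chr>         <dbl>  <dbl> <dbl>
#> 1 rf                1      1     1
#> 2 svm               1      1     1
#> 3 bpnn              1      1     1
```

Reading the numbers: `c1_rms` (epoch RMS of the strongest component) roughly
doubles from normal to forceful raise-eyebrows epochs — the simulator's
intensity factor is 2 — while the near-noise-floor frown epochs sit an order
of magnitude lower. All three classifiers separate the five forceful actions
perfectly on this clean synthetic session; that is a property of the
simulator's idealized assumptions (see the methods vignette), not a claim
about human data. Per-class detail comes from `tidy(res$report[[1]])`, a
confusion-matrix heat map from `autoplot(res$report[[1]])`.

A one-shot orchestration of the same flow, with artifacts and a hash
manifest:

```r
run_pipeline(list(seed = 1), out_dir = "run1", verbose = TRUE)
```

and a thin CLI over the same functions lives in `inst/cli/femg.R`
(subcommands `simulate`, `decode`, `preprocess`, `ica`, `features`, `train`,
`compare`, `pipeline`).

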