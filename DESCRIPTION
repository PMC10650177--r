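Package: perifemg
Title: Perifacial Surface EMG Simulation, Preprocessing and Movement Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with multichannel perifacial surface
    electromyography (sEMG) recorded by distal electrode arrays, where each
    electrode sees a volume-conducted mixture of several facial muscle
    sources. Provides a volume-conduction session simulator (burst-modulated
    Gaussian sources, geometric mixing, powerline/DC/broadband interference),
    a 24-bit ADC code/voltage and frame codec with a plain-text recording
    dialect, the standard sEMG conditioning chain (notch, Butterworth
    band-pass, DC removal, full-wave rectification, linear envelope),
    FastICA-style blind source separation, the eight classic time- and
    frequency-domain EMG features, device-agreement statistics (Spearman,
    energy ratio, linear and cross correlation), and facial-muscle-movement
    classification with one-vs-rest Gaussian-kernel SVM, random forest and a
    backpropagation neural network, including end-to-end pipeline
    orchestration with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
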