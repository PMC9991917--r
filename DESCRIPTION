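Package: neurowire
Title: Micro-Wire Electrophysiology: Simulation, Artifact Removal, Spectral
    Statistics, Stimulation Analysis and Memory Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for wearable intracranial micro-wire and macro-contact
    recordings: seed-deterministic synthetic data generators with ground truth
    (spike trains on 1/f backgrounds, motion artifacts, walking and verbal
    memory sessions, stimulation-burst sessions); ICA-based sharp-transient
    detection and interpolation with artifact-to-signal time ratio reporting;
    a minimal spike detection/clustering stage with cluster-acceptance rules,
    firing-rate estimation, SNR, yield and artifact-removal-impact metrics;
    Morse-wavelet scalograms, FFT and Welch power spectra, and fixed-cycle
    Morlet bandpower over a fine/coarse frequency grid; boundary-versus-inner
    bandpower statistics with subsample equalization and a paired sign-flip
    permutation test; device-concordance metrics (Hjorth parameters, kurtosis,
    artifact spike count, 60-Hz power); stimulation-burst scheduling, pulse
    rendering, template cross-correlation detection and propagation
    statistics; a causal phase-locked stimulation simulator scored by circular
    variance; and a two-branch CNN1D+LSTM decoder of verbal memory outcome
    with transfer learning, trained with an in-package RMSprop backpropagation
    engine, plus gradient-ascent filter visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
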