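Package: eegstates
Title: Multiscale EEG Biomarkers of Consciousness States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multiscale resting-state and perturbation-response EEG
    biomarkers used in consciousness assessment: windowed power spectral
    density with relative band power and band center frequency; aperiodic
    dynamics (autocorrelation window, detrended fluctuation analysis, 1/f
    exponent with oscillatory-peak pruning); information-theoretic complexity
    (Lempel-Ziv, permutation entropy, disorder-disequilibrium products);
    permutation cross-mutual information and phase lag index connectivity with
    graph-theoretic summaries (clustering coefficient, characteristic path
    length, small-worldness against degree-preserving nulls); polarity-
    invariant microstate segmentation with occurrence, duration and coverage
    statistics; and effective dimensionality of TMS-evoked responses.
    Includes seeded synthetic-EEG generators with state-contrast cohort
    presets and a group-comparison harness with Benjamini-Hochberg false
    discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
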