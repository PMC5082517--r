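Package: ictomark
Title: Model-Based Resting-State EEG Biomarkers of Generalized Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers functional brain networks from short segments of
    resting-state scalp EEG via the phase-locking factor with
    surrogate-based significance and zero-lag exclusion, embeds the
    inferred network in a mean-field phase-oscillator (Kuramoto-type)
    model with per-channel local coupling proportional to signal
    variance, and scores per-subject seizure likelihood by driving each
    node into synchrony. Includes two comparator biomarkers (occipital
    alpha-peak frequency and functional-network mean degree), a
    dual-threshold three-outcome leave-one-out classifier, Friedman-test
    comparison of biomarkers, a multichannel surrogate-EEG cohort
    generator, and EDF/CSV I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
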