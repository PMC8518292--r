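Package: copdls
Title: COPD Severity Classification from Multi-Channel Lung Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for grading chronic obstructive pulmonary
    disease (COPD) severity from multi-channel auscultation recordings.
    Recordings are synchronised on the initial cough, segmented and high-pass
    filtered, decomposed by ensemble empirical mode decomposition (EEMD) into
    intrinsic mode functions, and summarised through Hilbert marginal spectra
    into per-channel time-frequency-energy features. Channels and features are
    ranked with the reliefF weighting algorithm and classified with a
    radial-basis support vector machine under a repeated stratified 70/30
    split protocol, with naive-Bayes and gradient-boosted-tree baselines. A
    seeded synthetic lung-sound generator emulating cough bursts, breath-cycle
    noise and channel-localised adventitious components above 400 Hz makes the
    whole pipeline exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
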