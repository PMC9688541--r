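Package: p300prognosis
Title: P300 Detection Accuracy as a Prognosis Indicator in Disorders of
    Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, classification and cohort statistics
    for P300-based brain-computer-interface assessment of patients with
    disorders of consciousness. Generates oddball-paradigm EEG with a
    configurable P300 component on 1/f background noise, implements the
    standard ERP detection pipeline (zero-phase band-pass filtering, epoch
    extraction, decimated multi-channel feature vectors), trains two
    single-trial P300 detectors (a spatiotemporal convolutional network and a
    variational Bayesian multilayer perceptron with reparameterised weight
    sampling) under stratified k-fold cross-validation, computes the full
    confusion-matrix metric suite including F-beta, NPV and the area under
    the precision-recall curve, and runs the cohort-level statistics that
    relate per-patient detection accuracy to consciousness-recovery outcome,
    etiology and CRS-R score (pooled t-tests with Benjamini-Hochberg
    correction, Gaussian fits, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
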