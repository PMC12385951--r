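Package: eegpyramid
Title: Residual Dilated Pyramid Networks for EEG Seizure Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end classification of single-channel EEG recordings
    with a one-dimensional convolutional architecture that combines
    residual blocks, a cascaded dilated-convolution pyramid and a
    dual-pathway fusion of global-max-pooled and differential-entropy
    features, trained with label-smoothed cross-entropy.  Includes
    Bonn-format record input/output, windowed segmentation with
    Gaussian-perturbation augmentation, stratified k-fold cross-validation
    with t-based confidence intervals, ablation and entropy-variant
    sweeps, embedding export, and a seeded synthetic EEG generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
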