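Package: mseegnet
Title: Multiscale Spatial-Temporal Convolutional Networks for EEG-Based
    Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight multiscale
    spatial-temporal convolutional network for detecting Major Depressive
    Disorder from resting-state EEG. Provides the compact architecture
    (hemispheric spatial integration, multiscale depthwise temporal filter
    bank, separable high-level feature blocks with a projection skip, global
    average pooling), an ensemble-like classifier that majority-votes over
    sub-trials of a long inference trial, subject-level stratified ten-fold
    cross-validation with sliding-window augmentation, frequency-band ablation
    and gamma-energy correlation interpretability, and a synthetic EEG
    generator with a controllable gamma-band class effect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
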