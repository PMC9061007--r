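Package: osfpnet
Title: Object-Specific Four-Path Network for Carotid Plaque Ultrasound
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies a subject as symptomatic or asymptomatic from four
    arbitrarily sized B-mode ultrasound carotid-plaque regions of interest
    (left/right artery in transverse and longitudinal section). Implements a
    four-path convolutional network in which each path pairs a VGG16-style
    feature-extraction stage with an object-specific feature-downsampling
    stage: spatial pyramid pooling for the near-square transverse views and
    multilevel strip pooling for the elongated longitudinal views, so that
    inputs of any size yield fixed-length descriptors. Includes a speckle-
    textured synthetic cohort generator, subject-consistent scale/flip
    augmentation, patient-level 5-fold cross-validation with leakage guards,
    and confusion-matrix / ROC / paired-test evaluation with Holm-Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    pROC,
    png,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
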