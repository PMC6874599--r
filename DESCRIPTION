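Package: strainnet
Title: Instant Regional Brain Strain Estimation from Head Rotational
    Velocity with a Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@strainnet.dev",
           role = c("aut", "cre"))
Description: A surrogate for finite-element head injury models: a small
    convolutional neural network maps a three-channel head rotational
    velocity time history, encoded as a peak-aligned 3 x 201 image, to a
    scalar regional brain strain (95th-percentile maximum principal
    strain of the whole brain or corpus callosum, or corpus callosum
    fiber strain).  Includes the geometric data-augmentation scheme
    (axis permutation, random rigid rotation, conjugate-axis mirroring
    about the mid-sagittal plane, magnitude scaling into an
    injury-relevant band), the fixed-size input encoding with replicated
    padding, native training of the network (Adam, mean squared error,
    validation-based early stopping), k-fold cross-validation with
    repeated trials, the corrected resampled t-test for comparing
    cross-validated models, and a synthetic impact generator with a
    closed-form strain oracle so the full pipeline can be exercised
    without a finite-element solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
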