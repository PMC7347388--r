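Package: flymotor
Title: Motor Unit Recruitment Analysis for the Fly Leg
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring motor neuron recruitment at the Drosophila
    femur-tibia joint: calibration and dynamics of a flexible force probe
    (damped-oscillator model), segmentation of muscle calcium movies into
    motor-unit activity clusters, template spike detection with dynamic time
    warping for whole-cell and EMG recordings, reconstruction of true joint
    angles from tracked leg points via projected-arc geometry, spike-triggered
    force/velocity statistics, and bootstrap behavioral comparisons with
    false-discovery-rate control. Includes a seeded synthetic-data generator
    that emulates every input modality with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
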