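Package: menseg
Title: Two-Stage Adversarial Meniscus Segmentation with Object-Aware Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework for segmenting the medial and lateral
    meniscus in coronal knee MR volumes. Stage one localizes the menisci with a
    six-class 2D U-Net over whole slices and extracts margin-padded regions of
    interest using a standard-deviation margin rule; stage two refines the
    meniscus mask inside each 64x64 region with a conditional adversarial
    network whose discriminator is conditioned on an object-aware map (the
    element-wise product of the image with a probability map or ground truth).
    Ships a compact CNN engine (U-Net generator, encoder discriminator, manual
    backpropagation, Adam), a synthetic knee-phantom generator with
    ligament-like distractors for end-to-end testing, Dice/confusion-matrix
    evaluation with per-patient cohort summaries, and an experiment runner for
    the four-way ablation (whole-image U-Net, ROI U-Net, concatenation cGAN,
    object-aware cGAN).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
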