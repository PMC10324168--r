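Package: beamattack
Title: White-Box Adversarial Attacks on EEG Topographic-Map Seizure Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates electroencephalogram (EEG) adversarial samples by perturbing
    brain electrical activity mappings (BEAMs), the topographic maps of per-rhythm
    EEG power used in quantitative epilepsy diagnosis. Implements the full
    EEG-to-BEAM transform pipeline (wavelet-packet rhythm extraction, rhythm power,
    azimuthal-equidistant electrode projection, minimum-curvature topographic
    interpolation), convolutional and recurrent seizure-detection victim models
    with input-gradient services, a dense gradient-sign attack in BEAM space with
    frequency-domain imposition and wavelet-packet reconstruction back to EEG, a
    sparse differential-evolution attack with perturbation overflow, a dual-target
    modified attack, evaluation metrics (success rate, distortion, accuracy),
    a Gaussian-noise baseline, a transferability harness, and a synthetic
    seizure/background EEG generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    jsonlite,
    generics,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
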