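Package: headbci
Title: Predicting Voluntary Head Rotation from Pre-Movement EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for single-trial prediction of voluntary
    head rotations (left, right, or none) from short pre-movement EEG windows.
    Includes a seeded synthetic-session generator with a planted lateralized
    readiness-potential signature, IMU velocity-threshold onset detection,
    EEG preprocessing (amplitude-based rejection, 0.75-8 Hz band-pass,
    downsampling to 128 Hz), jittered pre-onset epoch extraction with class
    balancing and block-wise splitting, a multi-layer perceptron classifier
    with binomial chance-level thresholds, pseudo-online streaming evaluation
    with onset-locked probability traces, and pre-onset ERP lateralization
    topography.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
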