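Package: eegpolar
Title: Continuous Decoding of Hand-Motion Polar Angles from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for continuous regression of hand-motion polar
    angles from multichannel EEG recorded during bimanual circular tracking. Includes
    a synthetic-paradigm generator (circular-tracking kinematics with camera jitter and
    tracking dropouts; EEG with angle-locked low-frequency components, alpha/beta
    event-related desynchronization, movement-related cortical potentials, ocular
    artifacts, pink background and line noise), the full preprocessing chain (notch,
    zero-phase FIR band-pass, bad-channel interpolation, common average reference,
    dual-filter ICA ocular removal, epoching with baseline correction), polar-angle
    labeling, sliding-window dataset construction with trial-level cross-validation
    splits, six CNN and CNN-LSTM regression decoders trained with Adam and early
    stopping, permuted-label chance-level estimation with ANOVA comparison, and
    movement-related neural signatures (MRCP averages and Morlet-wavelet ERSP).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    ica,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
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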