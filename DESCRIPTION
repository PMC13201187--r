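Package: bcgsleep
Title: Contactless Sleep Staging from Ballistocardiography and Bedside Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying sleep stages from contactless
    recordings: beat-to-beat (JJ) intervals and 1 Hz vitals from a
    ballistocardiographic (BCG) bed sensor plus bedside audio. Computes
    time-, frequency- and nonlinear-domain heart-rate-variability features
    (Poincare geometry and asymmetry indices, sequential trend analysis,
    sample/approximate/Renyi entropy, detrended fluctuation analysis),
    cardiopulmonary coupling from cross-spectral power and coherence,
    and autocorrelation-based respiration features from audio. Assembles
    per-epoch 62-dimensional feature vectors, classifies 30-s epochs with
    a bidirectional LSTM feeding a dilated causal temporal convolutional
    network, and evaluates hypnograms under leave-one-subject-out
    cross-validation. Includes a synthetic session simulator so the whole
    pipeline runs end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
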