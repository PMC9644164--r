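Package: esngait
Title: Predicting Vertical Ground Reaction Forces from Shank Accelerometry
    with Echo State Networks
Version: 0.1.0
Authors@R:
    person("esngait", "authors", email = "esngait@example.org",
           role = c("aut", "cre"))
Description: Two-step gait analysis from wearable sensors: a leaky echo
    state network with a ridge-regression readout predicts continuous
    z-scored vertical ground reaction force (GRF) waveforms from tri-axial
    shank accelerometer signals, and foot-contact / foot-off events are
    subsequently detected from the predicted waveform by threshold
    crossings. Includes signal preprocessing (PCA re-orientation,
    zero-phase Butterworth high-pass, double integration, range
    normalization), stride segmentation, prediction-quality metrics
    (range-normalized RMSE, R squared, event timing MAE), the standard
    validation protocols (segmented-train / continuous-test with a
    continuation rule, training-size sweeps, leave-M-out cross-validation
    by trial), and a synthetic paired accelerometer/GRF trial generator so
    the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
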