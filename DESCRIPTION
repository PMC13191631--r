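Package: lfpstates
Title: Latent Oscillatory State Analysis of Cortico-Subthalamic Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers transient oscillatory network states in multichannel
    local field potential recordings from the subthalamic nucleus and motor
    cortex using a time-delay-embedded hidden Markov model with multivariate
    Gaussian emissions, characterizes each state's spectral and coherence
    fingerprint with Welch and Slepian multitaper estimators, computes
    per-window temporal statistics (fractional occupancy, lifetimes, visit
    intervals, switching rates), and relates state features to wearable-sensor
    motor-symptom scores through Gaussian GLMs with Benjamini-Hochberg false
    discovery rate control. Includes a Markov-switching signal generator with
    known ground truth for validation, readers and writers for delimited-text
    recordings and symptom logs, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
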