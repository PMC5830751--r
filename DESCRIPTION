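Package: oviclass
Title: Sheep Behaviour Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying sheep behaviour (lying,
    standing, walking) from body-mounted tri-axial accelerometer and
    gyroscope recordings. Provides a synthetic inertial-measurement-unit
    data generator with behaviour bout structure, magnitude and
    rate-of-change signal derivation, overlapping-window segmentation with
    majority labelling, a 44-dimensional feature set (moments, interquartile
    range, zero crossings, spectral entropy, dominant frequency, signal
    areas), a bagged ensemble of randomized decision trees, per-behaviour
    performance metrics with weighted Cohen's kappa for sensor-position
    agreement, and an embedded duty-cycle energy budget with battery-life
    projection, swept over sampling frequency, window size and sensor
    position.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
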