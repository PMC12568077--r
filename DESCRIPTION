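Package: gaitbouts
Title: Walking-Bout Segmentation from Shank-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting walking bouts in tri-axial accelerometer and
    gyroscope recordings from shank- or ankle-mounted inertial measurement
    units. Implements two complementary detectors: a residual-convolutional
    plus bidirectional LSTM activity classifier trained on sliding windows of
    raw sensor data, and a heuristic detector that tests for harmonic
    structure in the spectrum of the mediolateral angular velocity. Includes
    the full supporting pipeline: readers for PAMAP2 protocol files and
    generic IMU CSV recordings, sensor-to-shank calibration, label
    harmonization, windowing and participant-specific scaling, conversion of
    window predictions to per-sample gait masks and walking bouts, stride
    segmentation from mid-swing and heel-strike events, classification
    metrics with Wilson score intervals, and a synthetic gait-signal
    generator for end-to-end testing across gait-speed strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
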