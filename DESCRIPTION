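Package: ripvol
Title: Tidal-Volume Agreement Analysis for Dual-Band Respiratory
    Inductance Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify how accurately a dual-band respiratory
    inductance plethysmography (RIP) garment measures tidal volume
    against a reference spirometer.  Provides a synthetic dual-device
    dataset generator with known ground truth; signal preprocessing
    (Savitzky-Golay smoothing, thoraco-abdominal band summation, flow
    integration, cross-correlation time alignment); breath segmentation,
    cross-device breath matching and an unmatchable-data exclusion rule;
    spirometer-based least-squares calibration with cross-session
    calibration transfer; Bland-Altman agreement analysis against a
    priori accuracy criteria; and extraction of functional lung volumes
    (slow and forced vital capacity, one-second forced expiratory
    volume) from maneuver recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
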