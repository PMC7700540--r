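Package: imuhar
Title: Human Activity Recognition from Wearable Inertial Sensors with a
    Reweighted Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end recognition of physical activities from triaxial
    accelerometer, gyroscope and magnetometer streams. Denoises raw
    signals with median and moving-average filters, frames them into
    overlapping sliding windows, extracts a multi-fused bank of
    statistical, frequency and acoustic features (including
    empirical-mode-decomposition / Hilbert descriptors and spectral
    entropy), selects and reweights features with a genetic algorithm
    whose fitness averages linear-SVM and random-forest accuracies, and
    classifies activities by weighted nearest-template matching. Includes
    a synthetic multi-class signal generator, readers for raw
    comma-separated sensor logs, an evaluation protocol with per-class
    and macro accuracy reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
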