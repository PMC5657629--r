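Package: kinaction
Title: Skeleton-Based Action Recognition from Angular Kinematic Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recognizes human actions from 3D skeleton joint sequences using a
    per-frame angular spatio-temporal descriptor (hip-normalized pose plus
    bone-length-normalized angular velocity and acceleration over a five-frame
    window) and three modified k-nearest-neighbour procedures: a training-time
    frame-confidence KNN, a frame time-label estimator, and a
    confidence-weighted voting classifier that handles both segmented
    sequences and unsegmented streams. Includes motion-onset detection for
    regularizing irregularly segmented corpora, readers for a canonical
    skeleton CSV and the MSR-Action3D plain-text dialect, a forward-kinematics
    synthetic motion generator, and cross-subject evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
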