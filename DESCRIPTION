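Package: assistbci
Title: Adaptive P300 Decoding and Tabletop Perception for Assistive Robotics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hardware-free computational core of an intention-driven assistive
    drinking robot. Provides a synthetic oddball-paradigm EEG generator, a
    0.1-20 Hz preprocessing chain, Bayesian linear discriminant analysis with
    evidence-framework hyperparameter estimation, a self-adaptive online
    decoder with threshold-based early stopping and Wolpaw information
    transfer rate, organized point-cloud scene synthesis with region-growing
    plane extraction and two-times region-growing object segmentation, rigid
    camera-to-robot frame transforms, a small convolutional recognizer for
    beverage-container crops implemented in base R, and an end-to-end task
    simulator tying decoding, perception and a delivery state machine
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
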