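Package: stairgait
Title: Stride Segmentation, Gait Events and Stair-Ambulation Parameters from Foot-Worn IMUs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gait-analysis pipeline for continuous foot-worn inertial sensor
    recordings that include stair ascent and descent alongside level walking.
    Provides gravity-based sensor-to-body-frame alignment, a multiclass hidden
    Markov model (left-right stride sub-models plus a transition model) for
    stride-border segmentation, activity-independent gait-event detection
    (terminal contact, swing maximum, forward-acceleration maximum, initial
    contact, mid-stance), zero-velocity-update aided error-state Kalman filter
    trajectory reconstruction with Rauch-Tung-Striebel smoothing, spatial
    stride features (height, length, inclination), threshold-based stride-type
    classification, walking-bout assembly, digital mobility outcome summaries,
    pressure-insole reference event extraction, segmentation and event-timing
    evaluation metrics, and a kinematically self-consistent synthetic
    gait-signal generator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
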