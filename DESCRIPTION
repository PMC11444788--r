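Package: mostrack
Title: Multi-Object Tracking of Insect Flight in Laboratory Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracks small flying insects (such as mosquitoes) through
    grayscale laboratory video and turns per-frame detections into clean,
    evaluated flight trajectories. Provides a pluggable detection stage
    (a built-in intensity-threshold blob detector plus a reader for
    externally produced detection files), a Kalman-filter multi-object
    tracker with Hungarian assignment, Mahalanobis gating and appearance
    descriptors, removal of short-lived identities, cubic-spline
    interpolation of missing frames, occlusion-event extraction by
    bounding-box overlap, trajectory-accuracy statistics against ground
    truth, and a seeded synthetic flight-video generator with exact
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
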