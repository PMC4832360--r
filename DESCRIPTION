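Package: pilitrack
Title: Tracking and Force Inference for Pilus-Driven Twitching Motility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies bacterial twitching motility and type IV pilus
    retraction forces from time-lapse microscopy. Provides a synthetic
    movie generator with exact ground truth that emulates chains of cocci
    moving with train-like, crabwise, Brownian or static dynamics and
    micro-pillar force-sensor arrays deflected through a calibrated
    linear spring; sub-pixel normalized cross-correlation tracking of
    chains and pillar tips; instantaneous-velocity and axis-relative
    directionality statistics with mean-squared-displacement motion
    classification; and pillar deflection-to-force conversion with
    pull-event segmentation and force distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
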