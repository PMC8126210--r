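Package: neckstick
Title: Two-Joint Neck Model for Head Protraction from Rigid-Body Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-ball-joint kinematic neck model that infers the
    3-D position and protraction of the head relative to the thorax from the
    orientations of two rigid bodies (neck and sternum). Provides coordinate
    frame algebra and rigid-body pose estimation from optical marker triplets,
    linear least-squares identification of the seven model parameters
    (neck-stick length plus thorax and head offset vectors), residual error
    summaries, an anthropometric linear predictor of the neck-stick length
    from the palpable C2-C7 distance, a synthetic motion-capture simulator
    emulating standardized head-movement tasks, and a Monte-Carlo sensitivity
    analysis of the neck-length estimator under inflated marker-position and
    orientation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    yaml
Config/testthat/edition: 3
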