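Package: jmsound
Title: Texture-Based Classification of Cattle Jaw-Movement Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying cattle mastication (jaw-movement) events
    recorded as audio into bite, chew, chew-bite and sort classes. Audio
    segments are converted to normalized log-magnitude time-frequency images
    (short-time Fourier transform or Stockwell transform), 32 texture
    features are computed from four gray-level matrix methods (co-occurrence,
    spatial dependence, run length and dependence matrices), a genetic
    algorithm with a k-nearest-neighbour wrapper selects discriminative
    features, and six classifiers are trained and scored with per-class
    precision, recall and F1. A seeded synthetic-data generator emulates
    labeled mastication recordings so the full pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    nnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
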