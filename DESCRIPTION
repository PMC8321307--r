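Package: fallwatch
Title: Silhouette-Based Posture Recognition and Rule-Based Fall Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A single fixed camera watching an indoor scene can detect falls
    of a person living alone from the binary silhouette alone, preserving
    privacy. fallwatch implements the full pipeline: background modelling and
    subtraction with chromaticity-based shadow removal refined by
    gradient-direction correlation; a bounding-box angular projection
    histogram that describes a silhouette as an N x N grid of sector
    intersections plus three global angle features; a four-class posture
    classifier (bend, lie, sit, stand) using a radial-basis-function support
    vector machine; and a four-rule fall decision engine combining abnormal
    posture, floor coverage, posture-transition speed and inactivity.
    Synthetic silhouette, sequence and shadow-scene generators are included
    for end-to-end testing without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
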