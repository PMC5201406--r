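Package: hmdm
Title: Hidden Markov Driving Model for Stop/Go Behavior at Signalized
    Intersections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits discrete hidden Markov models of driver decision states
    (accelerate, decelerate, maintain speed, stop) from vehicle trajectories
    recorded as detection-line crossings on the approach to a signalized
    intersection.  Provides kinematics from frame-count crossing records, an
    81-symbol discretization of speed, headway, queue and signal observations,
    multi-sequence Baum-Welch and supervised maximum-likelihood estimation,
    Viterbi decoding, per-zone behavior-stability (emission-matrix 2-norm) and
    risk-index summaries for dilemma-zone analysis, dangerous-action warning
    prediction, and a synthetic intersection-approach simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
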