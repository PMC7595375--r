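Package: posturelab
Title: Posturography Analysis of Balance on a Tilting Support Surface
Version: 0.1.0
Authors@R: person("Posture", "Lab", email = "maintainer@posturelab.org",
    role = c("aut", "cre"))
Description: Tools for analysing standing balance experiments on a servo
    controlled tilt platform. Generates pseudo-random ternary sequence (PRTS)
    tilt stimuli from GF(3) shift registers, calibrates whole-body centre of
    mass from sway-rod and centre-of-pressure recordings, computes sway
    metrics (mean sway velocity, periodic and random sway components and
    their power), and runs two-way repeated-measures ANOVA with simple
    contrasts against an eyes-open reference. A feedback-controlled
    inverted-pendulum stander simulator reproduces the experimental design
    (four visual conditions, three platform conditions) so the full pipeline
    runs without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
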