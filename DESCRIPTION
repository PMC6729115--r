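Package: attriphase
Title: Detecting Phases of Dropout Attrition in Item-by-Item Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying phases of dropout attrition in
    item-by-item survey completion data. Implements three detectors: a
    user-specified threshold scan on per-question dropout proportions, a
    logistic generalized linear mixed model on cumulative dropout
    indicators with adjacent-question contrasts, and a discrete-time
    survival analysis of the per-question dropout hazard. Includes a
    phase-structured monotone-dropout simulator and an evaluation engine
    that measures type I error and sensitivity of each detector under
    constant, two-phase, and three-phase attrition patterns, with
    boundary-choice histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    graphics,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
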