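Package: ranevs
Title: Eye-Voice Coordination Analysis for Rapid Automatized Naming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for analysing eye-voice coordination during rapid
    automatized naming (RAN) tasks. Builds stimulus-array layouts with
    area-of-interest (AOI) tilings, reads gaze sample tables and per-item
    vocal articulation intervals, detects fixations with a velocity-threshold
    (I-VT) classifier, computes eye-voice span, perseveration and regression
    counts, applies run-level quality-control exclusion rules, aggregates
    runs into symbolic and non-symbolic conditions, and fits group-level
    mixed models with diagnosis-by-culture designs. Includes a synthetic
    gaze-and-voice simulator with known ground truth so the full pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
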