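Package: hdstate
Title: Cause Identification for Hazardous Driver States from Multimodal Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.com")
Description: Pipeline for classifying the cause of a hazardous driver
    state (cell-phone distraction, sleep deprivation, dense traffic, snowy
    weather) from physiological signals, vehicle kinematics and
    questionnaire scores. Includes a synthetic factorial-study generator
    with configurable condition effects, zero-phase signal filtering,
    extraction of 61 physiological, kinematics and driver-characteristics
    features, per-session baseline and min-max normalization, stepwise
    forward F-test feature selection, leave-one-out cross-validated SVM,
    logistic-regression and decision-tree classification in independent
    and augmented schemes, and repeated-measures workload validation on
    NASA-TLX scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
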