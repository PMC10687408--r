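Package: persist305
Title: Lactation Persistency Prediction at the Insemination Decision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling dairy-cow lactation curves from
    milking-robot visit records and for predicting lactation persistency
    (the half-life of milk production implied by the MilkBot decay
    parameter at day in milk 305) at candidate insemination moments.
    Provides the closed-form MilkBot curve mathematics, prior-regularised
    incremental curve fitting, an editing cascade for robot-visit data
    (24-h yield reconstruction, lactation- and fit-level filters, breeding
    status, herd-year aggregation), standardised linear prediction models
    with evaluation metrics, and a synthetic multi-herd milking-record
    generator so the whole pipeline can be validated end to end against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
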