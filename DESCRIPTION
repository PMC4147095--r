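Package: crcdqi
Title: Scoring and Psychometric Evaluation of the Colorectal Cancer
    Screening Decision Quality Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Colorectal Cancer Screening Decision Quality
    Instrument (CRC-DQI): a standardized knowledge score with explicit
    missing-data rules, a goal-concordance score derived from a logistic
    preference model linking goal importance ratings to screening test
    choice, and a composite binary decision-quality indicator. Also
    provides the instrument's psychometric evaluation protocol
    (test-retest intraclass correlation, item retention diagnostics,
    discriminant and construct validity contrasts, mode-effect and
    feasibility summaries, brief-version reproducibility) and a seeded
    synthetic-cohort generator with known ground truth so every
    estimator can be checked by parameter recovery without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
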