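Package: gaitmob
Title: Smartphone Gait and Mobility Measures with Longitudinal PROM Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phenotyping pipeline for duty-cycled smartphone sensor
    streams. Reads raw accelerometer and GPS CSV files, derives six daily
    measures (step count, gait cadence, stride acceleration, home time,
    distance traveled, number of significant locations), applies valid-day
    filtering and survey alignment, scores patient-reported outcome measures
    (ECOG PS, EQ-5D-5L, PROMIS PF 6b), and fits random-intercept/random-slope
    linear mixed-effects association and trend models. Includes a fully
    parameterised synthetic-cohort generator with planted ground truth so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
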