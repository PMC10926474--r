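Package: phenodd
Title: Degree-Day Phenology Models for Insect Trap-Catch Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Develops and validates degree-day models that forecast the
    seasonal phenology of adult insect trap-catch, as used for Japanese
    beetle (Popillia japonica) monitoring. Provides simple-average and
    half-day sine-wave degree-day accumulation with lower and upper
    developmental thresholds and a configurable biofix, reduction of raw
    trap observations to cumulative-proportion emergence curves, maximum-
    likelihood fitting of a log-logistic emergence curve to degree-day
    accumulation, exhaustive grid search over biofix dates, thresholds and
    calculation methods scored by Lin's concordance correlation coefficient
    with AIC tie-breaking, hold-out validation statistics, and a synthetic
    weather and trap-catch generator for desk-scale testing of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
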