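Package: tastequiv
Title: Equivalence Inference for Randomized Single-Sample Taste Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inferential pipeline for randomized, double-blind,
    single-sample discrimination (taste) tests analysed as a two-arm 2x2
    contingency table. Provides odds-ratio and AUC estimators of
    distinguishability, a five-region equivalence test and confidence
    interval on the odds ratio, percentile bootstrap confidence intervals
    for the AUC, analytic and Monte-Carlo power and minimal sample size for
    the boundary test, a participant-level study simulator, and report
    generation, together with the summary counts of a randomized water
    taste test conducted in the Taipei metropolis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
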