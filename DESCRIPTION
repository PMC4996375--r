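Package: survconsensus
Title: Two-Cohort Consensus Screening of Survival-Associated Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis pipeline for discovering genes whose microarray
    expression consistently associates with patient survival across two
    independent cohorts profiled on different platforms. For every probe it
    trains a small single-input neural network to classify short versus long
    survivors at several dichotomization cut-offs and ranks probes by blind
    validation error, fits a univariate Cox proportional-hazards model via an
    in-house Newton-Raphson partial-likelihood maximizer, intersects the four
    candidate gene sets (two methods by two cohorts), applies t-test and
    expression-direction consistency filters, and reports a ranked consensus
    gene list together with a combined chance-probability statistic.
    Includes a synthetic two-platform cohort generator with planted
    survival-signal genes for end-to-end validation, and inter-rater
    concordance statistics (Cohen's kappa, pairwise group t-tests) for
    categorical immunohistochemistry scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
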