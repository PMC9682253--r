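Package: beatbayes
Title: Bayesian Observer Modeling of Systematic Errors in Rhythm Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling how listeners judge the timing of the final
    beat of an isochronic rhythm. Implements a Bayesian observer with a
    temporally asymmetric Gamma impulse response, a lognormal prior over
    inter-beat intervals, and a family of loss functions including a
    better-early-than-late shift; Monte-Carlo simulation of two-alternative
    forced-choice experiments over factorial stimulus designs; coordinate-
    descent fitting of observer parameters to response counts by Pearson
    chi-square; the group statistics used in timing psychophysics (exact
    binomial tests, Cohen's h, Kendall trend tests, population prevalence,
    cross-subject medians); and a synthetic-cohort generator for end-to-end
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
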