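Package: skinrate
Title: Rate-Dependence Analysis of Burn Skin Uniaxial Tensile Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing loading-rate (in)dependence of soft-tissue
    mechanics from uniaxial tensile tests. Converts force-displacement
    records to nominal stress-strain curves, extracts ultimate tensile
    stress, ultimate tensile strain and toughness, fits the
    Veronda-Westmann hyperelastic law by bounded nonlinear least squares,
    screens outliers by interquartile-range fences, runs a
    normality-gated univariate hypothesis-testing decision tree with
    Cohen's d effect sizes and noncentral-t minimum-sample-size power
    analysis, and evaluates multiclass separability by leave-one-out
    cross-validated multinomial logistic regression with confusion-matrix
    metrics (accuracy, MCC, Fowlkes-Mallows index, adjusted Rand index).
    Includes a seeded synthetic-cohort generator calibrated by
    quartile-matched lognormal parameter laws, so the whole pipeline is
    testable without access to specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    nnet,
    pracma,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
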