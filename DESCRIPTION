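Package: hkmeta
Title: Random-Effects Meta-Analysis and Meta-Regression with
    Hartung-Knapp Inference via Weighted Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the normal-normal random-effects model for
    meta-analysis and meta-regression and provides both conventional
    (normal-pivot) and Hartung-Knapp (t-pivot, scaled-variance)
    inference for the average effect and for moderator coefficients.
    Exposes the equivalence between these methods and weighted least
    squares regression with error variances known exactly versus known
    up to a constant of proportionality, including the identity between
    the Hartung-Knapp scaling factor and the weighted mean squared
    error of the regression. Includes restricted maximum likelihood and
    DerSimonian-Laird estimators of the between-study variance,
    effect-size conversion for standardized mean differences (Hedges' g
    with the exact small-sample correction) and 2x2 tables (log odds
    ratios), constrained Hartung-Knapp variants that bound the scaling
    factor, a Monte Carlo harness for confidence-interval coverage
    studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    yaml
Config/testthat/edition: 3
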