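Package: nipaired
Title: Non-Inferiority Inference for Binary Matched Pairs with Missing
    Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Confidence intervals and non-inferiority tests for the risk
    difference from binary matched-pairs data in which single observations
    of a pair may be missing. Implements Nam's score test and Tango's
    restricted-MLE score confidence interval on completely observed pairs,
    a multiple-imputation Wald interval with Rubin's rules, the hybrid
    Wald-type interval of Tang and colleagues based on Wilson score
    bounds, and a marginal logistic model fitted by generalized estimating
    equations with an exchangeable working correlation, sandwich
    covariance and a delta-method interval that uses all observed
    outcomes including singleton clusters. Also provides a generator for
    correlated Bernoulli pairs with MCAR/MAR missingness, a Monte-Carlo
    harness for power, coverage and interval width, asymptotic and
    simulation-based sample-size routines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
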