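Package: gsdci
Title: Confidence Intervals After Two-Stage Group Sequential Trials with a
    Binary Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Point estimators and nine confidence interval procedures for the
    difference in response probabilities after a two-arm, two-stage group
    sequential trial with one-sided O'Brien-Fleming efficacy stopping.
    Implements the standard Wald interval, the stagewise-ordering exact
    (final unconditional) interval and median unbiased estimator, repeated
    confidence intervals, an adjusted asymptotic interval based on the
    moments of the stopped maximum likelihood estimator, parametric and
    randomization-based bootstrap intervals, exact conditional and restricted
    conditional intervals given the stopping stage, the conditional maximum
    likelihood estimator, and penalized-likelihood estimation with
    decision-consistent conditional bootstrap intervals.  A vectorized
    simulation engine evaluates coverage, width and test-decision consistency
    of every method, overall and conditional on the stopping stage, across
    scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
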