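Package: hapstar
Title: Bayesian Structured Additive Regression for Household Air Pollution
    and Adverse Birth Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow studying the association between household air
    pollution (unclean cooking fuel) and adverse birth outcomes (stillbirth,
    low birth weight, preterm birth) in DHS-style cohorts. Provides a
    synthetic cohort generator with nested mothers, spatially structured
    area effects on an adjacency graph and fuel-wealth collinearity;
    contingency-table descriptives (prevalence ratios with Katz confidence
    intervals, odds ratios with Woolf intervals, chi-square, Fisher and
    Welch tests); a Bayesian probit structured additive regression model
    with a P-spline age smooth, mother-level random intercepts, intrinsic
    CAR structured plus exchangeable unstructured spatial effects, fitted
    by Gibbs sampling with Albert-Chib data augmentation; and a four-model
    ladder compared by the deviance information criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
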