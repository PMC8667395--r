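Package: gboins
Title: Generalized Bayesian Optimal Interval Designs with Shrinkage Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for phase I dose-finding trials with
    binary, quasi-binary (toxicity-grade score) and continuous toxicity
    endpoints. Implements the generalized Bayesian optimal interval (gBOIN)
    design, whose fixed escalation/de-escalation boundaries minimise the
    probability of an incorrect dose-transition decision under three point
    hypotheses, and its adaptive extension (gBOINS) in which the hypothesis
    points are chosen by the uniformly most powerful Bayesian test and the
    decision boundaries shrink toward the target as the per-dose sample size
    grows. Includes the sequential trial engine with overdose-control
    elimination, isotonic-regression (PAVA) selection of the maximum tolerated
    dose, a library of benchmark scenarios, and a replicated-trial simulator
    computing standard operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
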