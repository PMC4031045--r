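Package: priorbelief
Title: Bayesian Prior-Belief and Reinforcement-Learning Models of Choice
    in Pavlovian Conditioning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Pavlovian conditioning task in which subjects
    observe fractal stimuli paired probabilistically with binary outcomes
    and then choose between each fractal and an explicitly cued reference
    option. Implements a Bayesian observer with a Beta prior over each
    stimulus's outcome probability and a softmax choice rule, together
    with a family of temporal-difference learning models with optional
    asymmetric learning rates and a free initial value. Provides
    per-subject maximum-likelihood estimation, BIC model comparison,
    synthetic cohorts with a planted correlation between a trait score
    and the prior mean, and the group-level statistics used to test
    whether trait optimism behaves as a prior belief: performance curves,
    trait-parameter correlations with Bonferroni correction,
    optimist/pessimist splits, Fisher r-to-z comparisons across
    experiments, and stratified analyses of sparsely versus densely
    observed stimuli.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    jsonlite,
    withr,
    lhs
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
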