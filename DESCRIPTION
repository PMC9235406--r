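Package: artbayes
Title: Hierarchical Bayesian Modelling of the Angling Risk Task
Version: 0.1.0
Authors@R:
    person("ART", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing the Angling Risk Task (ART),
    a sequential risk/reward decision task in the BART family. Provides the
    probability schedule and pre-generated max-cast design of the task, the
    two-parameter cognitive model (risk propensity gamma-plus and behavioral
    consistency beta) with its censored Bernoulli likelihood, a synthetic
    cohort generator with covariates, hierarchical Bayesian estimation of
    individual- and group-level parameters by Metropolis-within-Gibbs MCMC
    with split R-hat and effective-sample-size diagnostics, and the task's
    outcome statistics: adjusted score, default-prior (JZS) Bayes factors
    for two-sample and one-way designs, permutation tests, and Pearson
    associations with TIV-corrected volumetric covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
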