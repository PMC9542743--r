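Package: socialsampler
Title: Distributed Bayesian Inference in Multigenerational Populations
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of belief transmission in discrete
    multigenerational networks, where each generation decides about binary
    environment features from shared Bernoulli evidence and the decisions of
    a uniformly sampled member of the previous generation. Implements the
    social-sampling heuristic (resample-until-accept with likelihood-based
    acceptance) whose population-level behaviour performs distributed
    Bayesian inference, five alternative decision rules (asocial probability
    matching, asocial Bayesian matching, asocial utility maximisation, naive
    copying, and probability-matching social sampling), evidence censoring
    by a companion's design, and a metrics pipeline measuring information
    accumulation against the ideal Bayesian posterior: popularity/evidence
    correlations, fixed-effects regression, and one-step-ahead
    predicted-popularity mean squared error for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
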