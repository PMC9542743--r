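---
title: "Social sampling as distributed Bayesian inference: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social sampling as distributed Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialsampler)
```

## The model

A population is organised in discrete generations of N agents. The
environment is a vector of F binary features x, fixed per trial. At each
generation every agent sees the same block of J Bernoulli outcomes per
feature, emitted with probability `theta1` when the feature is true and
`theta0` when it is false; `S` counts the positive outcomes in a block, and
the block likelihood of the evidence under a belief d is
`theta_d^S (1 - theta_d)^(J - S)`.

The core decision rule, *social sampling*, treats the previous generation as
a prior: an agent samples a companion uniformly at random, accepts the
companion's belief with probability proportional to the likelihood of the
newly observed evidence under that belief, and otherwise resamples. Because
the rounds of this chain are i.i.d., the marginal probability of ending on
belief 1 is exactly

```
q = p L1 / (p L1 + (1 - p) L0),
```

the Bayesian update of the previous popularity `p` by the current block —
see `social_update()` and the Monte-Carlo checks in the test suite. Chaining
this over generations makes popularity track the *ideal posterior*
conditioned on all evidence the population has seen
(`ideal_posterior()`, a log-space two-hypothesis computation with the
sufficient statistic `S_cum / (t J)`). A finite population is a particle
filter for that posterior: unbiased in expectation, noisy at order
`1/sqrt(N)` per generation.

Six decision rules are implemented (`predicted_popularity()` gives each
one's analytic one-step-ahead prediction):

* `social_sampling_bayes` — likelihood-ratio acceptance as above;
* `social_sampling_matching` — acceptance probability equal to the recent
  positive-evidence fraction `S/J` for belief 1 and `(J-S)/J` for belief 0;
* `naive_copy` — adopt the sampled companion's decisions unchanged;
* `nonsocial_matching` — Bernoulli(`S/J`), ignoring the population;
* `nonsocial_bayes_matching` — probability matching on the single-block
  uniform-prior posterior;
* `nonsocial_utility_max` — the posterior mode, fair coin at a tie.

The two social-sampling rules are mixtures: a proportion `rho` of agents
decides socially and `1 - rho` falls back on an asocial rule. The mixture
partner is chosen like-for-like (`social_sampling_bayes` with
`nonsocial_bayes_matching`, `social_sampling_matching` with
`nonsocial_matching`); the alternative pairings are not distinguishable from
the published description, and keeping each mixture inside one strategy
family makes `rho = 0` a clean degeneration. In the uncensored task `rho`
defaults to 0.19, the share of trials on which participants in that task
observably resampled social information (a lower bound on social decision
making); in the censored task all decisions are social and `rho = 1`.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `theta1`, `theta0` | evidence emission probabilities (per outcome) | 0.6 / 0.3 | uncensored-task setting; censored presets use symmetric `theta`, `1 - theta` |
| `J` | outcomes per feature per generation | 4 | the four lab tests / flights per trial |
| `N` | agents per generation | 20 | shift size in both tasks (5 in the small censored conditions) |
| `T_gen` | generations | 10 | both tasks ran 10 generations |
| `F_feat` | features per trial | 8 | eight classifications / parts |
| `rho` | social proportion | 0.19 uncensored, 1 censored | see above |
| `max_resamples` | accept/reject cap | 1000 | acceptance is bounded away from 0 for interior theta; the cap falls back to the last sampled companion and is effectively never hit |

## The two evidence regimes

`evidence_lag = 0` (uncensored): deciders at generation g observe the block
drawn for their own generation, for every feature; generation 0 applies an
asocial rule to its block (`first_generation`, default
`nonsocial_bayes_matching`; the published design implies but does not state
that the first generation saw evidence, so this is configurable).

`evidence_lag = 1` with `censored = TRUE` (censored): deciders observe the
*previous* generation's block, and only for features their sampled
companion chose; generation 0 guesses uniformly. Positive evidence is coded
on the canonical side (`y = 1` favours `x = 1`), so a symmetric strength
`theta` becomes `theta1 = theta`, `theta0 = 1 - theta`.

### Censoring semantics

The published description leaves the interaction of censoring with the
resample chain informal; the package fixes it as follows. Each agent
records exactly one companion. That companion is simultaneously (a) the
round-1 candidate of every feature's accept/reject chain and (b) the source
of the censoring mask (the companion's decision vector). Later rounds
resample beliefs uniformly from the previous generation while evidence
visibility stays as the mask fixed it. Three consequences, each asserted in
the tests:

1. a censored feature (`J_eff = 0`) has a flat likelihood, so round 1
   always accepts — the agent copies the companion exactly;
2. if every previous design includes every feature, the censored run is
   bit-for-bit identical to the uncensored run under the same seed;
3. in the uncensored regime the round-1 companion is itself uniform, so the
   marginal stays exactly the closed form `q`.

The censored one-step prediction used by `model_mse()` is the exact
companion average of this process: with probability `p_prev` the companion
chose the feature, in which case the decision is 1 with probability
`A1 + (1 - A1) q` (`A1` the max-normalised acceptance of belief 1), and
with probability `1 - p_prev` it is a copy of the companion's 0. Asocial
rules under a censored feature face no evidence and decide Bernoulli(0.5).
Naive copying predicts `p_prev` in both regimes.

## Numerical choices

* Likelihoods and the ideal posterior are computed in log space with the
  `0 * log(0) = 0` convention, so degenerate `theta` in {0, 1} is exact;
  evidence impossible under both hypotheses raises a classed
  `degenerate_evidence_error` rather than returning NaN.
* The acceptance normaliser is the max of the two beliefs' likelihoods.
  Any constant keeping acceptance in (0, 1] gives the same marginal (the
  chain is i.i.d. across rounds); `norm_scale` exposes this for testing,
  and the closed form is compared against a truncated geometric-series
  enumeration oracle at tolerance 1e-12.
* Closed-form comparisons in the tests use relative tolerance 1e-12;
  Monte-Carlo comparisons use explicit binomial standard errors.
* Ties: `nonsocial_utility_max` flips a fair coin exactly at posterior 0.5
  (which occurs only when `theta1 + theta0 = 1` and `2S = J`, or when
  `theta1 = theta0`).
* All randomness flows from one root seed through named substreams
  (`substream_seed()`), keyed by network, trial and purpose, so any single
  network can be reproduced without replaying the whole suite.
* Decisions are independent across features given the evidence *within the
  decision rule*, but agents copy or sample whole companions, so features
  of one network share the companion genealogy. They are therefore not
  independent replicates of the population process — replicate-based tests
  in the package simulate independent networks instead.

## What the generator emulates — and what it does not

The simulator reproduces the stated experimental worlds: shared per-
generation evidence blocks (perfectly correlated across agents of a
generation), uniform companion sampling with replacement, the preset
tables (one uncensored preset of 3 networks x 10 generations x 20 agents,
F = 8, J = 4, theta = 0.6/0.3, 2 trials; five censored conditions with
repetitions 2, 1, 1, 2, 2, 4 trials each), and design-based censoring.
It does not emulate: participants' interim within-trial decisions after
each of the four tests (only final per-generation decisions are modelled);
heterogeneous or learned `theta`; payment-driven attention; non-uniform or
strategic companion choice; or belief misreporting. A green test
establishes that the algorithms have their stated mathematical properties
on data from this stated world — it says nothing about fit to human data,
which are not packaged.

## Known limitations

* The finite-population gap between popularity and the ideal posterior is
  *not* a single binomial deviation: each generation inherits the previous
  generation's gap through the update map, so the variance of the gap in
  binomial-SE units exceeds 1 (its scale factor follows
  `v_t ≈ c_t v_{t-1} + 1` with `E[c_t] = 1`). A per-generation 3-SE band at
  N = 10,000 over 10 generations is exceeded in roughly 40% of runs of the
  true model; the acceptance test asserting that band is kept as stated and
  fails at the precommitted seed. The replication-averaged convergence
  check (`convergence_check()`, mean absolute gap strictly decreasing over
  N in {20, 200, 2000}) is the robust form of the same claim and passes.
* The exact forms of the three asocial rules and of the matching
  acceptance for belief 0 are reconstructions: the published description
  states the fractions for positive beliefs and the package applies them
  symmetrically.
* Censored-regime deciders integrate exactly one companion's evidence;
  whether participants could combine flights from several prior designs is
  unknown.
* Model comparison weighs all analysis rows equally when pooling MSE
  across networks and trials; per-network pooling is an untested
  alternative.
* YAML configuration files are not supported (no YAML parser among the
  package's dependencies); use JSON.
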