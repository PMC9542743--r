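# socialsampler

Agent-based simulation and analysis of belief transmission in
multigenerational populations, for researchers in computational cognitive
science, cultural evolution and collective behaviour who want to study when
a chain of short-lived, cognitively cheap generations accumulates
information like a single ideal Bayesian observer.

## The model

Each generation of N agents decides whether each of F binary environment
features x_i is true. Evidence arrives as generation-shared blocks of J
Bernoulli outcomes per feature, positive with probability θ1 if x_i = 1 and
θ0 if x_i = 0; S counts the positives in a block. The core decision rule is
**social sampling**: an agent draws a companion a′ uniformly from the
previous generation and accepts their decision d with probability
proportional to the block likelihood θ_d^S (1 − θ_d)^(J−S), resampling
until acceptance. The marginal of this accept/reject chain is the Bayes
update of the previous generation's popularity p by the new block,

    q = p·L1 / (p·L1 + (1 − p)·L0),

so a population of social samplers is a particle filter whose popularity
tracks the **ideal posterior** — the uniform-prior posterior conditioned on
*all* evidence the population has observed, with sufficient statistic
S_≤t/(tJ). The package implements six decision rules (Bayesian and
probability-matching social sampling with a social proportion ρ, naive
copying, and three asocial rules), two evidence regimes (uncensored, and
censored by a sampled companion's design), and the metrics that quantify
accumulation: popularity/evidence correlations, fixed-effects regression of
popularity on evidence fractions, and one-step-ahead predicted-popularity
MSE for model comparison.

## Worked example

Simulate the built-in uncensored preset (3 networks × 10 generations × 20
agents, F = 8, J = 4, θ1 = 0.6, θ0 = 0.3, 2 trials) under Bayesian social
sampling with ρ = 0.19, then analyse it:

```r
library(socialsampler)
cfg  <- preset_config("exp1", rho = 0.19, seed = 42)
runs <- run_experiment(cfg)
rows <- analysis_rows(runs)           # 432 rows: 8 x 9 x 2 x 3

correlate(rows, "total_evidence_fraction", "popularity")$r
#> [1] 0.6387682
correlate(rows, "last_evidence_fraction", "popularity")$r
#> [1] 0.9125405

model_mse(rows, rho = 0.19)
#> <model_comparison> one-step-ahead predicted-popularity MSE
#>                      model      mse rank
#> 1    social_sampling_bayes 0.009584    1
#> 2 nonsocial_bayes_matching 0.011628    2
#> 3 social_sampling_matching 0.013738    3
#> 4       nonsocial_matching 0.015885    4
#> 5    nonsocial_utility_max 0.100781    5
#> 6               naive_copy 0.102517    6

regress_popularity(rows)
#> <popularity_regression> n = 432, residual df = 427
#>                      term estimate     se      t   p_value
#> 1             (Intercept)  0.03902 0.0165  2.364  1.85e-02
#> 2 total_evidence_fraction  0.16425 0.0431  3.808  1.60e-04
#> 3  last_evidence_fraction  0.84366 0.0249 33.873 4.65e-123
#> 4                network2  0.00338 0.0132  0.256  7.98e-01
#> 5                network3  0.01970 0.0133  1.483  1.39e-01
```

Popularity correlates strongly with both the cumulative and the most recent
evidence fraction, and total evidence stays predictive after controlling
for the last block — the signature of information accumulating across
generations. The generating model also wins the MSE comparison. Convergence
towards the ideal posterior improves with generation size:

```r
convergence_check(N_values = c(20, 200, 2000), reps = 20, seed = 42)
#> <convergence_report> popularity vs ideal posterior
#>      N mean_abs_gap max_abs_gap
#> 1   20     0.055069     0.24775
#> 2  200     0.025993     0.09003
#> 3 2000     0.005071     0.01491
#> mean gap decreasing in N: TRUE; largest N within 3 SE: FALSE
```

## Command line

`inst/cli/socialsampler` exposes the same pipeline as subcommands:

```sh
Rscript inst/cli/socialsampler simulate --preset exp1 \
    --model social_sampling_bayes --rho 0.19 --seed 7 --out run/
Rscript inst/cli/socialsampler evaluate \
    --decisions run/decisions.csv --evidence run/evidence.csv --out run/analysis/
Rscript inst/cli/socialsampler convergence-check --N 20,200,2000 --seed 1
Rscript inst/cli/socialsampler suite --seed 1 --out suite/
```

`simulate` writes `decisions.csv`, `evidence.csv`, `trajectory.csv`,
`config.json` and a checksummed `manifest.json` (identical seeds give
identical bytes); `evaluate` rebuilds the analysis from the flat CSVs and
writes `analysis_rows.csv`, `regression.json`, `correlations.json` and
`model_mse.csv`. Custom runs take `--config file.json` with
`experiment_config()` fields.

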