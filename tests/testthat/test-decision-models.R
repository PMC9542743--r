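test_that("evidence_likelihood evaluates the Bernoulli-block likelihood", {
  # empty block: likelihood 1 under either belief
  expect_equal(evidence_likelihood(0, S = 0, J = 0, 0.6, 0.3), 1)
  expect_equal(evidence_likelihood(1, S = 0, J = 0, 0.6, 0.3), 1)

  expect_equal(evidence_likelihood(1, S = 2, J = 4, 0.6, 0.3),
               0.6^2 * 0.4^2)
  expect_equal(evidence_likelihood(0, S = 2, J = 4, 0.6, 0.3),
               0.3^2 * 0.7^2)

  # theta1 == theta0: beliefs indistinguishable for every S
  for (S in 0:4) {
    expect_equal(evidence_likelihood(1, S, 4, 0.45, 0.45),
                 evidence_likelihood(0, S, 4, 0.45, 0.45))
  }
  expect_error(evidence_likelihood(1, S = 5, J = 4, 0.6, 0.3),
               class = "domain_error")
})

test_that("acceptance_probability normalizes by the better-supported belief", {
  # the belief with the larger likelihood is always accepted
  expect_equal(acceptance_probability(1, S = 4, J = 4, 0.6, 0.3), 1)
  ratio <- (0.3^4) / (0.6^4)
  expect_equal(acceptance_probability(0, S = 4, J = 4, 0.6, 0.3), ratio)

  # no evidence: accept anything (degenerates to naive copying)
  expect_equal(acceptance_probability(0, 0, 0, 0.6, 0.3), 1)
  expect_equal(acceptance_probability(1, 0, 0, 0.6, 0.3), 1)

  # contradictory degenerate evidence has zero likelihood under both beliefs
  expect_error(acceptance_probability(1, S = 2, J = 4, theta1 = 1, theta0 = 1),
               class = "degenerate_evidence_error")
})

test_that("social_update is the Bayes update of popularity and is monotone", {
  # consensus absorbing
  expect_equal(social_update(0, 4, 4, 0.6, 0.3), 0)
  expect_equal(social_update(1, 0, 4, 0.6, 0.3), 1)
  # uninformative evidence leaves the prior untouched
  expect_equal(social_update(0.37, 2, 4, 0.5, 0.5), 0.37)
  expect_equal(social_update(0.37, 0, 0, 0.6, 0.3), 0.37)

  expect_equal(social_update(0.5, 4, 4, 0.6, 0.3),
               0.6^4 / (0.6^4 + 0.3^4))

  # matching closed form uses evidence fractions as weights
  expect_equal(social_update(0.3, 1, 4, acceptance = "matching"),
               0.3 * 0.25 / (0.3 * 0.25 + 0.7 * 0.75))

  # monotone non-decreasing in p_prev for fixed evidence, both variants
  p <- seq(0, 1, by = 0.05)
  for (S in 0:4) {
    expect_true(all(diff(social_update(p, S, 4, 0.6, 0.3)) >= 0))
    expect_true(all(diff(social_update(p, S, 4,
                                       acceptance = "matching")) >= 0))
  }
  expect_error(social_update(0.5, 2, 4, theta1 = 1, theta0 = 1),
               class = "degenerate_evidence_error")
})

test_that("resample-until-accept marginal matches the closed form and its enumeration oracle", {
  # geometric-series enumeration converges to the same closed form
  for (p in c(0.1, 0.5, 0.9)) {
    for (S in 0:4) {
      a1 <- acceptance_probability(1, S, 4, 0.6, 0.3)
      a0 <- acceptance_probability(0, S, 4, 0.6, 0.3)
      expect_equal(chain_enum(p, a1, a0), social_update(p, S, 4, 0.6, 0.3),
                   tolerance = 1e-12)
    }
  }

  # unanimous previous generation forces the decision
  set.seed(21)
  expect_true(all(social_sampling_decision(rep(1L, 20), 0, 4, 0.6, 0.3,
                                           n = 50) == 1L))

  # Monte-Carlo marginal vs closed form (100,000 draws, 4 SE)
  set.seed(22)
  d <- social_sampling_decision(prev_vec(0.5, 10), S = 3, J = 4,
                                theta1 = 0.6, theta0 = 0.3, n = 1e5)
  q <- social_update(0.5, 3, 4, 0.6, 0.3)
  expect_lt(abs(mean(d) - q), 4 * mc_se(q, 1e5))

  # J = 0 reduces bit-for-bit to copying a uniform companion
  set.seed(23)
  prev <- prev_vec(0.3, 10)
  d0 <- social_sampling_decision(prev, 0, 0, 0.6, 0.3, n = 2000)
  set.seed(23)
  expect_identical(as.integer(d0),
                   prev[sample.int(10, 2000, replace = TRUE)])
  expect_true(all(attr(d0, "resamples") == 1L))
})

test_that("the marginal is invariant to the acceptance normalizer", {
  q <- social_update(0.4, 1, 4, 0.6, 0.3)
  set.seed(24)
  d_scaled <- social_sampling_decision(prev_vec(0.4, 10), 1, 4, 0.6, 0.3,
                                       n = 1e5, norm_scale = 0.4)
  expect_lt(abs(mean(d_scaled) - q), 4 * mc_se(q, 1e5))
  # smaller normalizer only lengthens the loop
  expect_gt(mean(attr(d_scaled, "resamples")), 1)
})

test_that("matching acceptance follows the recent-evidence fraction", {
  expect_equal(matching_acceptance(1, S = 4, J = 4), 1)
  expect_equal(matching_acceptance(0, S = 4, J = 4), 0)
  expect_equal(matching_acceptance(1, S = 2, J = 4), 0.5)
  expect_equal(matching_acceptance(0, S = 2, J = 4), 0.5)
  expect_equal(matching_acceptance(1, S = 0, J = 0), 1) # no evidence: copy

  # Monte-Carlo vs the derived closed form at p = 0.3, S = 1, J = 4
  set.seed(25)
  d <- social_sampling_decision(prev_vec(0.3, 10), 1, 4, n = 1e5,
                                acceptance = "matching")
  qm <- 0.3 * (1 / 4) / (0.3 * (1 / 4) + 0.7 * (3 / 4))
  expect_lt(abs(mean(d) - qm), 4 * mc_se(qm, 1e5))
})

test_that("asocial rules give the stated decision probabilities", {
  set.seed(26)
  # utility maximizer is deterministic off ties
  expect_true(all(asocial_decision("nonsocial_utility_max", 4, 4, 0.6, 0.3,
                                   n = 20) == 1L))
  expect_true(all(asocial_decision("nonsocial_matching", 0, 4, 0.6, 0.3,
                                   n = 20) == 0L))

  # Bayesian matcher accepts at the uniform-prior single-block posterior
  set.seed(27)
  d <- asocial_decision("nonsocial_bayes_matching", 3, 4, 0.6, 0.3, n = 5e4)
  q <- enum_posterior(3, 4, 0.6, 0.3)
  expect_lt(abs(mean(d) - q), 4 * mc_se(q, 5e4))

  expect_error(asocial_decision("naive_copy", 1, 4, 0.6, 0.3),
               class = "config_error")
  expect_error(predicted_popularity("not_a_model", 0.5, 1, 4, 0.6, 0.3),
               class = "config_error")
})

test_that("predicted_popularity composes the mixture correctly", {
  # naive copying predicts the previous popularity identically
  p <- seq(0, 1, 0.1)
  expect_equal(predicted_popularity("naive_copy", p, 2, 4, 0.6, 0.3), p)

  # rho = 0 collapses each social model onto its asocial partner
  for (S in 0:4) {
    expect_equal(
      predicted_popularity("social_sampling_bayes", 0.4, S, 4, 0.6, 0.3,
                           rho = 0),
      predicted_popularity("nonsocial_bayes_matching", 0.4, S, 4, 0.6, 0.3))
    expect_equal(
      predicted_popularity("social_sampling_matching", 0.4, S, 4, 0.6, 0.3,
                           rho = 0),
      predicted_popularity("nonsocial_matching", 0.4, S, 4, 0.6, 0.3))
  }

  # rho = 0.19 is the stated convex combination of the two components
  q_soc <- social_update(0.4, 3, 4, 0.6, 0.3)
  q_asoc <- enum_posterior(3, 4, 0.6, 0.3)
  expect_equal(
    predicted_popularity("social_sampling_bayes", 0.4, 3, 4, 0.6, 0.3,
                         rho = 0.19),
    0.19 * q_soc + 0.81 * q_asoc)

  # monotone non-decreasing in p_prev for the social predictions
  for (S in 0:4) {
    expect_true(all(diff(predicted_popularity(
      "social_sampling_bayes", p, S, 4, 0.6, 0.3, rho = 0.19)) >= 0))
    expect_true(all(diff(predicted_popularity(
      "social_sampling_matching", p, S, 4, 0.6, 0.3, rho = 1,
      censored = TRUE)) >= 0))
  }
  # all predictions are probabilities
  for (m in c("nonsocial_matching", "nonsocial_bayes_matching",
              "nonsocial_utility_max", "naive_copy",
              "social_sampling_matching", "social_sampling_bayes")) {
    for (cz in c(FALSE, TRUE)) {
      v <- predicted_popularity(m, rep(p, each = 5), rep(0:4, 11), 4,
                                0.6, 0.3, rho = 0.5, censored = cz)
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("censored one-step prediction matches the simulated censored step", {
  # single censored generation from an exact-popularity start
  for (model in c("social_sampling_bayes", "social_sampling_matching",
                  "naive_copy")) {
    n_big <- 4000
    init <- matrix(rep(prev_vec(0.6, 10), n_big / 10), n_big, 1)
    cfg <- experiment_config(
      T_gen = 2, N = n_big, F_feat = 1, J = 4, theta1 = 0.6, theta0 = 0.4,
      censored = TRUE, model = model, rho = 1, seed = 31,
      init_decisions = init)
    tr <- run_network(cfg)$trajectory
    g1 <- tr[tr$generation == 1, ]
    pred <- predicted_popularity(model, 0.6, g1$S_last, 4, 0.6, 0.4,
                                 rho = 1, censored = TRUE)
    expect_lt(abs(g1$popularity - pred),
              4 * sqrt(max(pred * (1 - pred), 1e-4) / n_big))
  }
})
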