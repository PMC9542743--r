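test_that("generation stepping has the stated fixed points and marginals", {
  # naive copying from a unanimous generation stays unanimous
  cfg <- experiment_config(T_gen = 5, N = 12, F_feat = 3, J = 4,
                           model = "naive_copy", seed = 51,
                           init_decisions = matrix(1L, 12, 3))
  run <- run_network(cfg)
  expect_true(all(run$trajectory$popularity == 1))

  # guessing first generation is Bernoulli(0.5) per decision
  cfg2 <- experiment_config(T_gen = 2, N = 100, F_feat = 50, J = 4,
                            censored = TRUE, model = "naive_copy", seed = 52)
  g0 <- run_network(cfg2)$trials[[1]]$generations[[1]]$decisions
  expect_lt(abs(mean(g0) - 0.5), 4 * sqrt(0.25 / length(g0)))

  # one Bayesian social-sampling step hits the closed form at large N
  n_big <- 5000
  cfg3 <- experiment_config(T_gen = 2, N = n_big, F_feat = 1, J = 4,
                            theta1 = 0.6, theta0 = 0.3,
                            model = "social_sampling_bayes", rho = 1,
                            seed = 53,
                            init_decisions = matrix(rep(prev_vec(0.4, 10),
                                                        n_big / 10)))
  tr3 <- run_network(cfg3)$trajectory
  g1 <- tr3[tr3$generation == 1, ]
  q <- social_update(0.4, g1$S_last, 4, 0.6, 0.3)
  expect_lt(abs(g1$popularity - q), 3 * sqrt(q * (1 - q) / n_big))
})

test_that("run_network is deterministic and handles the base case", {
  cfg <- experiment_config(T_gen = 1, N = 10, F_feat = 4, J = 4, seed = 54)
  tr <- run_network(cfg)$trajectory
  expect_identical(unique(tr$generation), 0L) # only the initial generation

  cfg2 <- preset_config("exp1", seed = 55)
  a <- as_decisions_table(run_network(cfg2, network_id = 2))
  b <- as_decisions_table(run_network(cfg2, network_id = 2))
  expect_identical(a, b)
  # different networks draw from different substreams
  c3 <- as_decisions_table(run_network(cfg2, network_id = 3))
  expect_false(identical(a$decision, c3$decision))
})

test_that("presets match the built-in condition table", {
  cfg <- preset_config("exp1", seed = 56)
  expect_equal(cfg$n_networks, 3L)
  expect_equal(cfg$N, 20L)
  expect_equal(cfg$T_gen, 10L)
  expect_equal(cfg$theta1, 0.6)
  expect_equal(cfg$theta0, 0.3)
  expect_false(cfg$censored)
  # 10 generations x 20 agents = 200 simulated agents per network
  d <- as_decisions_table(run_network(cfg))
  d1 <- d[d$trial == 1, ]
  expect_equal(nrow(unique(d1[, c("generation", "agent")])), 200)

  c3 <- preset_config("exp2-c3")
  expect_equal(c3$N, 20L)
  expect_equal(c3$J, 4L)
  expect_equal(c3$theta1, 0.8)
  expect_equal(c3$theta0, 0.2)
  expect_true(c3$censored)
  c5 <- preset_config("exp2-c5")
  expect_equal(c5$N, 5L)
  expect_equal(c5$J, 1L)
  expect_equal(c5$theta1, 0.6)

  expect_error(preset_config("exp3"), class = "config_error")

  # the full censored suite honours the tabled repetitions: 8 networks
  runs <- run_condition_suite(presets = paste0("exp2-c", 1:5), seed = 57)
  expect_length(runs, 8)
})

test_that("shared evidence makes utility maximizers unanimous", {
  cfg <- experiment_config(T_gen = 6, N = 15, F_feat = 8, J = 4,
                           theta1 = 0.6, theta0 = 0.3,
                           model = "nonsocial_utility_max",
                           first_generation = "nonsocial_utility_max",
                           seed = 58)
  tr <- run_network(cfg)$trajectory
  # theta = 0.6/0.3, J = 4 admits no posterior ties, so all agents agree
  expect_true(all(tr$popularity %in% c(0, 1)))
})

test_that("censoring with an all-features design reproduces the uncensored run", {
  init <- matrix(1L, 10, 4) # every design includes every part
  base <- list(T_gen = 5, N = 10, F_feat = 4, J = 4, theta = 0.7,
               model = "social_sampling_bayes", rho = 1, seed = 59,
               evidence_lag = 1L, first_generation = "guess",
               init_decisions = init)
  cens <- do.call(experiment_config, c(base, censored = TRUE))
  open <- do.call(experiment_config, c(base, censored = FALSE))
  expect_identical(as_decisions_table(run_network(cens))$decision,
                   as_decisions_table(run_network(open))$decision)
})

test_that("censored masks come from the companion and force exact copies", {
  cfg <- experiment_config(T_gen = 4, N = 25, F_feat = 8, J = 4,
                           theta = 0.6, censored = TRUE,
                           model = "social_sampling_bayes", seed = 60)
  run <- run_network(cfg)
  gens <- run$trials[[1]]$generations
  for (g in 2:4) {
    gen <- gens[[g]]
    prev <- gens[[g - 1]]$decisions
    expect_identical(gen$mask, prev[gen$companions, , drop = FALSE])
    # censored features (companion did not choose them) are copied: 0
    expect_true(all(gen$decisions[gen$mask == 0] == 0L))
  }
})
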