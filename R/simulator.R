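# End-to-end multigenerational network simulation.
#
# Two evidence regimes are supported through `evidence_lag`:
#   lag 0 (gem-classification regime): deciders at generation g observe the
#     block emitted for their own generation, uncensored; generation 0
#     decides asocially from its block.
#   lag 1 (spaceship regime): deciders at generation g observe the block of
#     generation g - 1 through the design of a uniformly sampled companion
#     (censored), and generation 0 guesses at random with no evidence. An
#     agent's own flights are recorded for the next generation but never
#     inform the agent's own decisions.

EXP2_CONDITIONS <- data.frame(
  condition = paste0("exp2-c", 1:5),
  reps = c(2L, 1L, 1L, 2L, 2L),
  N = c(20L, 20L, 20L, 5L, 5L),
  J = c(4L, 1L, 4L, 4L, 1L),
  theta = c(0.6, 0.6, 0.8, 0.6, 0.6)
)

#' Built-in experimental condition table
#'
#' Parameter settings of the built-in presets: the uncensored
#' gem-classification network (`exp1`) and the five censored spaceship
#' conditions (`exp2-c1` .. `exp2-c5`), which vary generation size N,
#' evidence amount J and symmetric evidence strength theta
#' (`theta1 = theta`, `theta0 = 1 - theta`).
#'
#' @return data frame with one row per preset.
#' @export
condition_table <- function() {
  rbind(
    data.frame(condition = "exp1", reps = 3L, N = 20L, J = 4L, theta = NA),
    EXP2_CONDITIONS
  )
}

#' Build a simulation configuration
#'
#' @param n_networks independent networks to simulate.
#' @param T_gen number of generations per network.
#' @param N agents per generation.
#' @param F_feat number of binary features per trial.
#' @param J evidence outcomes per feature per generation.
#' @param theta1,theta0 emission probabilities; alternatively give the
#'   symmetric strength `theta` (then `theta1 = theta`, `theta0 = 1 - theta`).
#' @param theta symmetric evidence strength, overrides `theta1`/`theta0`.
#' @param censored censor each agent's evidence by its companion's design.
#' @param model decision model id (see `MODEL_IDS`).
#' @param rho proportion of social decision making for the two
#'   `social_sampling_*` models.
#' @param n_trials independent trials (fresh truth and evidence) per network.
#' @param seed root seed; all networks/trials draw from named substreams.
#' @param evidence_lag 0 = deciders see their own generation's block;
#'   1 = they see the previous generation's block.
#' @param first_generation `"guess"` (uniform decisions, no evidence) or an
#'   asocial model id applied to generation 0's block (lag-0 regime only).
#' @param max_resamples cap on the accept/reject loop.
#' @param condition label recorded in output tables.
#' @param init_decisions optional N x F binary matrix overriding generation
#'   0 (used for controlled starts in tests and convergence checks).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_networks = 1, T_gen = 10, N = 20, F_feat = 8,
                              J = 4, theta1 = 0.6, theta0 = 0.3, theta = NULL,
                              censored = FALSE,
                              model = "social_sampling_bayes", rho = 1,
                              n_trials = 1, seed = 1,
                              evidence_lag = if (censored) 1L else 0L,
                              first_generation =
                                if (censored) "guess"
                                else "nonsocial_bayes_matching",
                              max_resamples = 1000,
                              condition = NA_character_,
                              init_decisions = NULL) {
  if (!is.null(theta)) {
    ss_check(theta >= 0 && theta <= 1, "config_error",
             "theta must be in [0, 1]")
    theta1 <- theta
    theta0 <- 1 - theta
  }
  for (nm in c("n_networks", "T_gen", "N", "F_feat", "n_trials")) {
    v <- get(nm)
    ss_check(is.numeric(v) && length(v) == 1 && v >= 1 && v == floor(v),
             "config_error", sprintf("%s must be a positive integer", nm))
  }
  ss_check(J >= 0 && J == floor(J), "config_error",
           "J must be a non-negative integer")
  check_model_id(model)
  ss_check(rho >= 0 && rho <= 1, "config_error", "rho must be in [0, 1]")
  ss_check(evidence_lag %in% c(0L, 1L), "config_error",
           "evidence_lag must be 0 or 1")
  ss_check(identical(first_generation, "guess") ||
           first_generation %in% ASOCIAL_MODELS,
           "config_error",
           "first_generation must be 'guess' or an asocial model id")
  if (first_generation != "guess" && evidence_lag == 1L) {
    ss_error("config_error",
             "lag-1 regime has no generation-0 evidence; use first_generation = 'guess'")
  }
  if (!is.null(init_decisions)) {
    ss_check(is.matrix(init_decisions) && nrow(init_decisions) == N &&
             ncol(init_decisions) == F_feat && is_binary(init_decisions),
             "config_error", "init_decisions must be a binary N x F matrix")
  }
  structure(
    list(n_networks = as.integer(n_networks), T_gen = as.integer(T_gen),
         N = as.integer(N), F_feat = as.integer(F_feat), J = as.integer(J),
         theta1 = theta1, theta0 = theta0, censored = isTRUE(censored),
         model = model, rho = rho, n_trials = as.integer(n_trials),
         seed = seed, evidence_lag = as.integer(evidence_lag),
         first_generation = first_generation,
         max_resamples = as.integer(max_resamples), condition = condition,
         init_decisions = init_decisions),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_config> %s%s\n",
           "  %d network(s) x %d trial(s): T = %d, N = %d, F = %d, J = %d\n",
           "  theta1 = %g, theta0 = %g, censored = %s, lag = %d, rho = %g\n"),
    x$model, if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$n_networks, x$n_trials, x$T_gen, x$N, x$F_feat, x$J,
    x$theta1, x$theta0, x$censored, x$evidence_lag, x$rho))
  invisible(x)
}

#' Configuration preset for a built-in condition
#'
#' @param preset `"exp1"` or `"exp2-c1"` .. `"exp2-c5"`.
#' @param model decision model to simulate under.
#' @param rho social proportion; defaults to 0.19 for `exp1` (the estimated
#'   share of social decisions in the uncensored task) and 1 for the
#'   censored conditions (all decisions are social there).
#' @param seed root seed.
#' @return an [experiment_config()].
#' @export
preset_config <- function(preset, model = "social_sampling_bayes",
                          rho = NULL, seed = 1) {
  if (identical(preset, "exp1")) {
    return(experiment_config(
      n_networks = 3, T_gen = 10, N = 20, F_feat = 8, J = 4,
      theta1 = 0.6, theta0 = 0.3, censored = FALSE, model = model,
      rho = rho %||% 0.19, n_trials = 2, seed = seed,
      condition = "exp1"))
  }
  i <- match(preset, EXP2_CONDITIONS$condition)
  if (is.na(i)) {
    ss_error("config_error",
             paste0("unknown preset '", preset, "'; expected exp1 or ",
                    paste(EXP2_CONDITIONS$condition, collapse = ", ")))
  }
  row <- EXP2_CONDITIONS[i, ]
  experiment_config(
    n_networks = row$reps, T_gen = 10, N = row$N, F_feat = 8, J = row$J,
    theta = row$theta, censored = TRUE, model = model, rho = rho %||% 1,
    n_trials = 4, seed = seed, condition = preset)
}

# one generation step for every model; prev_d is the previous generation's
# N_prev x F decision matrix and S the evidence counts the deciders see
step_generation <- function(prev_d, S, config) {
  n <- config$N
  f <- config$F_feat
  n_prev <- nrow(prev_d)
  ss_check(ncol(prev_d) == f && length(S) == f, "config_error",
           "model/evidence shape mismatch")
  th1 <- config$theta1
  th0 <- config$theta0
  J <- config$J
  model <- config$model

  comp <- sample.int(n_prev, n, replace = TRUE)
  mask <- if (config$censored) prev_d[comp, , drop = FALSE] else NULL
  res <- matrix(1L, n, f)

  if (model == "naive_copy") {
    d <- prev_d[comp, , drop = FALSE]
  } else if (model %in% ASOCIAL_MODELS) {
    p <- asocial_prob(model, S, rep_len(J, f), th1, th0)
    pm <- matrix(rep(p, each = n), n, f)
    if (config$censored) pm[mask == 0] <- 0.5
    d <- matrix(rbinom(n * f, 1L, pm), n, f)
  } else {
    acc_type <- if (model == "social_sampling_bayes") "bayes" else "matching"
    w <- acceptance_weights(S, rep_len(J, f), th1, th0, acc_type)
    m <- pmax(w$w1, w$w0)
    if (any(m == 0)) {
      ss_error("degenerate_evidence_error",
               "evidence has zero acceptance weight under both beliefs")
    }
    a1 <- w$w1 / m
    a0 <- w$w0 / m
    social <- if (config$rho < 1) runif(n) < config$rho else rep(TRUE, n)

    cand <- prev_d[comp, , drop = FALSE]
    colid <- col(cand)
    acc_p <- matrix(ifelse(cand == 1L, a1[colid], a0[colid]), n, f)
    if (config$censored) acc_p[mask == 0] <- 1 # flat likelihood: pure copy
    accepted <- matrix(runif(n * f), n, f) < acc_p
    accepted[!social, ] <- TRUE # asocial share handled below
    active <- which(!accepted)
    rounds <- 1L
    while (length(active) && rounds < config$max_resamples) {
      cols <- ((active - 1L) %/% n) + 1L
      nd <- prev_d[cbind(sample.int(n_prev, length(active), replace = TRUE),
                         cols)]
      cand[active] <- nd
      res[active] <- res[active] + 1L
      keep <- runif(length(active)) < ifelse(nd == 1L, a1[cols], a0[cols])
      active <- active[!keep]
      rounds <- rounds + 1L
    }
    # cap hit: the last sampled companion's decision stands (already in cand)
    d <- cand
    if (any(!social)) {
      partner <- ASOCIAL_PARTNER[[model]]
      p <- asocial_prob(partner, S, rep_len(J, f), th1, th0)
      pm <- matrix(rep(p, each = n), n, f)
      if (config$censored) pm[mask == 0] <- 0.5
      k <- which(!social)
      d[k, ] <- rbinom(length(k) * f, 1L, pm[k, , drop = FALSE])
    }
  }
  list(decisions = d, companions = comp, resamples = res, mask = mask)
}

run_trial <- function(config, network_id, trial) {
  set.seed(substream_seed(config$seed,
                          c("network", network_id, "trial", trial)))
  f <- config$F_feat
  n <- config$N
  T_gen <- config$T_gen
  J <- config$J
  spec <- feature_spec(sample_truth(f), config$theta1, config$theta0)
  blocks <- generate_evidence(spec, J, T_gen)
  # block whose counts generation g's deciders see (NULL when none)
  decision_block <- function(g) {
    i <- g + 1L - config$evidence_lag
    if (i < 1L) NULL else blocks[[i]]
  }

  gens <- vector("list", T_gen)
  for (g in seq_len(T_gen) - 1L) {
    if (g == 0L) {
      if (!is.null(config$init_decisions)) {
        d <- config$init_decisions
      } else if (config$first_generation == "guess") {
        d <- matrix(rbinom(n * f, 1L, 0.5), n, f)
      } else {
        S0 <- decision_block(0L)$positive_counts
        p <- asocial_prob(config$first_generation, S0, rep_len(J, f),
                          config$theta1, config$theta0)
        d <- matrix(rbinom(n * f, 1L, rep(p, each = n)), n, f)
      }
      gens[[1]] <- list(decisions = d, companions = rep(NA_integer_, n),
                        resamples = matrix(0L, n, f), mask = NULL)
    } else {
      blk <- decision_block(g)
      gens[[g + 1L]] <- step_generation(gens[[g]]$decisions,
                                        blk$positive_counts, config)
    }
  }

  S_mat <- vapply(blocks, function(b) b$positive_counts, numeric(f))
  S_mat <- matrix(S_mat, nrow = f) # f x T
  pop <- vapply(gens, function(gn) popularity(gn$decisions), numeric(f))
  pop <- matrix(pop, nrow = f)

  g_idx <- seq_len(T_gen) - 1L
  t_eff <- g_idx + 1L - config$evidence_lag # blocks pooled by gen g deciders
  S_cum_blocks <- matrix(t(apply(S_mat, 1, cumsum)), nrow = f) # f x T
  S_cum <- matrix(0, f, T_gen)
  S_last <- matrix(NA_real_, f, T_gen)
  for (g in g_idx) {
    te <- t_eff[g + 1L]
    if (te >= 1L) {
      S_cum[, g + 1L] <- S_cum_blocks[, te]
      S_last[, g + 1L] <- S_mat[, te]
    }
  }
  n_obs <- t_eff * J
  traj <- data.frame(
    network = network_id,
    condition = config$condition,
    trial = trial,
    generation = rep(g_idx, each = f),
    feature = rep(seq_len(f), T_gen),
    popularity = as.vector(pop),
    p_prev = as.vector(cbind(NA_real_, pop[, -T_gen, drop = FALSE])),
    S_last = as.vector(S_last),
    J = J,
    S_cum = as.vector(S_cum),
    n_obs = rep(n_obs, each = f),
    theta1 = config$theta1,
    theta0 = config$theta0,
    censored = config$censored
  )
  traj$total_evidence_fraction <-
    ifelse(traj$n_obs > 0, traj$S_cum / traj$n_obs, NA_real_)
  traj$last_evidence_fraction <-
    ifelse(traj$J > 0 & !is.na(traj$S_last), traj$S_last / traj$J, NA_real_)
  traj$ideal_posterior <- ideal_posterior(
    traj$S_cum, t = pmax(traj$n_obs, 0) / max(J, 1),
    J = max(J, 1), theta1 = config$theta1, theta0 = config$theta0)

  list(truth = spec$truth, blocks = blocks, generations = gens,
       trajectory = traj)
}

#' Simulate one multigenerational network
#'
#' Runs `n_trials` independent trials (fresh truth, evidence and agents) of
#' `T_gen` chained generations under the configured decision model. All
#' randomness derives from named substreams of `config$seed`, so a run is
#' fully reproducible.
#'
#' @param config an [experiment_config()].
#' @param network_id integer label (also the substream key).
#' @return object of class `network_run`: list with `config`, `network_id`,
#'   `trials` (per-trial truth, evidence blocks and generation records) and
#'   `trajectory` (per feature-generation data frame; see [analysis_rows()]).
#' @export
run_network <- function(config, network_id = 1L) {
  ss_check(inherits(config, "experiment_config"), "config_error",
           "config must be an experiment_config")
  trials <- lapply(seq_len(config$n_trials),
                   function(tr) run_trial(config, network_id, tr))
  traj <- do.call(rbind, lapply(trials, `[[`, "trajectory"))
  structure(
    list(config = config, network_id = as.integer(network_id),
         trials = trials, trajectory = traj),
    class = "network_run"
  )
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("<network_run> network %d (%s), %d trial(s) x %d generations x %d agents\n",
              x$network_id,
              if (is.na(x$config$condition)) x$config$model
              else paste(x$config$condition, x$config$model),
              x$config$n_trials, x$config$T_gen, x$config$N))
  invisible(x)
}

#' Simulate all networks of one configuration
#'
#' @param config an [experiment_config()]; `config$n_networks` networks are
#'   run with independent substreams.
#' @return list of [run_network()] results.
#' @export
run_experiment <- function(config) {
  lapply(seq_len(config$n_networks), function(i) run_network(config, i))
}

#' Run a suite of built-in condition presets
#'
#' Simulates every requested preset with its tabled number of repetitions
#' (networks), each on an independent seed substream.
#'
#' @param presets character vector of preset names; default all six.
#' @param model decision model id used for every run.
#' @param rho social proportion (`NULL` = preset default).
#' @param seed root seed.
#' @return flat list of `network_run` objects.
#' @export
run_condition_suite <- function(presets = condition_table()$condition,
                                model = "social_sampling_bayes", rho = NULL,
                                seed = 1) {
  runs <- list()
  for (p in presets) {
    cfg <- preset_config(p, model = model, rho = rho,
                         seed = substream_seed(seed, c("preset", p)))
    runs <- c(runs, run_experiment(cfg))
  }
  runs
}

#' Analysis rows for the metrics pipeline
#'
#' One row per (network, trial, feature, social generation): observed
#' popularity, the previous generation's popularity, the evidence fractions
#' and the ideal posterior. Generation 0 (asocial or guessing) is excluded,
#' matching the convention that only social generations are analysed.
#'
#' @param runs a `network_run` or a list of them.
#' @return data frame of analysis rows.
#' @export
analysis_rows <- function(runs) {
  if (inherits(runs, "network_run")) runs <- list(runs)
  traj <- do.call(rbind, lapply(runs, `[[`, "trajectory"))
  rows <- traj[traj$generation >= 1, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
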