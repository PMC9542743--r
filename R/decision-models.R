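# The six decision rules and their analytic one-step-ahead predictions.
#
# Social sampling: an agent samples a companion from the previous generation
# uniformly at random and accepts their belief d with probability proportional
# to the likelihood of the agent's newly observed evidence under d,
# resampling until acceptance. The marginal accept-state probability equals
# the Bayesian update of the previous generation's popularity by the current
# evidence block, which is what makes the population a particle filter for
# the ideal posterior.

MODEL_IDS <- c("nonsocial_matching", "nonsocial_bayes_matching",
               "nonsocial_utility_max", "naive_copy",
               "social_sampling_matching", "social_sampling_bayes")

SOCIAL_MODELS <- c("naive_copy", "social_sampling_matching",
                   "social_sampling_bayes")
ASOCIAL_MODELS <- setdiff(MODEL_IDS, SOCIAL_MODELS)

# asocial rule each social-sampling mixture falls back on (like with like)
ASOCIAL_PARTNER <- c(social_sampling_matching = "nonsocial_matching",
                     social_sampling_bayes = "nonsocial_bayes_matching")

check_model_id <- function(model_id) {
  ss_check(is.character(model_id) && length(model_id) == 1 &&
           model_id %in% MODEL_IDS,
           "config_error",
           paste0("unknown model id; expected one of: ",
                  paste(MODEL_IDS, collapse = ", ")))
  model_id
}

check_counts <- function(S, J) {
  ss_check(all(J >= 0) && all(J == floor(J)), "config_error",
           "J must be a non-negative integer")
  ss_check(all(S >= 0) && all(S <= J), "domain_error",
           "S must satisfy 0 <= S <= J")
}

#' Bernoulli-block likelihood of the evidence under a belief
#'
#' `theta_d^S * (1 - theta_d)^(J - S)` with `theta_1 = theta1`,
#' `theta_0 = theta0`. The empty block (J = 0) has likelihood 1 under either
#' belief. Vectorized over `d` and `S`.
#'
#' @param d binary belief (0 or 1), the companion's decision.
#' @param S number of positive outcomes, `0 <= S <= J`.
#' @param J number of outcomes in the block.
#' @param theta1,theta0 emission probabilities.
#' @return likelihood in `[0, 1]`.
#' @export
#' @examples
#' evidence_likelihood(1, S = 2, J = 4, theta1 = 0.6, theta0 = 0.3)
evidence_likelihood <- function(d, S, J, theta1, theta0) {
  ss_check(is_binary(d), "config_error", "d must be binary")
  check_counts(S, J)
  th <- ifelse(d == 1, theta1, theta0)
  # 0^0 = 1 in R, so theta in {0, 1} degenerates correctly
  th^S * (1 - th)^(J - S)
}

#' Acceptance probability of a companion's belief
#'
#' Likelihood of the evidence under the companion's belief, normalized by the
#' larger of the two beliefs' likelihoods so the more supported belief is
#' always accepted. Any normalizer keeping both probabilities in (0, 1]
#' yields the same resample-until-accept marginal; the max normalizer merely
#' minimizes the expected loop length. `norm_scale` in (0, 1] rescales both
#' acceptance probabilities (exposed to make that invariance testable).
#'
#' @inheritParams evidence_likelihood
#' @param d_companion the sampled companion's binary decision.
#' @param norm_scale optional extra scaling of the normalizer, in (0, 1].
#' @return acceptance probability in `(0, 1]`.
#' @export
acceptance_probability <- function(d_companion, S, J, theta1, theta0,
                                   norm_scale = 1) {
  ss_check(norm_scale > 0 && norm_scale <= 1, "config_error",
           "norm_scale must be in (0, 1]")
  l1 <- evidence_likelihood(1L, S, J, theta1, theta0)
  l0 <- evidence_likelihood(0L, S, J, theta1, theta0)
  m <- pmax(l1, l0)
  if (any(m == 0)) {
    ss_error("degenerate_evidence_error",
             "evidence has zero likelihood under both beliefs")
  }
  ifelse(d_companion == 1, l1, l0) / m * norm_scale
}

#' Probability-matching acceptance probability
#'
#' The probability-matching social sampler accepts a companion's positive
#' belief with probability equal to the fraction of positive outcomes in the
#' most recent evidence block, S/J, and a negative belief with the complement
#' fraction (J - S)/J. An empty block is uninformative and always accepted
#' (the sampler degenerates to naive copying).
#'
#' @inheritParams acceptance_probability
#' @return acceptance probability in `[0, 1]`.
#' @export
matching_acceptance <- function(d_companion, S, J, norm_scale = 1) {
  ss_check(norm_scale > 0 && norm_scale <= 1, "config_error",
           "norm_scale must be in (0, 1]")
  check_counts(S, J)
  out <- ifelse(d_companion == 1, S, J - S) / ifelse(J == 0, 1, J)
  ifelse(J == 0, 1, out) * norm_scale
}

# weights (proportional acceptance rates) for belief 1 / belief 0
acceptance_weights <- function(S, J, theta1, theta0,
                               acceptance = c("bayes", "matching")) {
  acceptance <- match.arg(acceptance)
  if (acceptance == "bayes") {
    w1 <- evidence_likelihood(1L, S, J, theta1, theta0)
    w0 <- evidence_likelihood(0L, S, J, theta1, theta0)
  } else {
    if (any(J == 0)) {
      w1 <- w0 <- rep_len(1, length(S))
      keep <- J > 0
      w1[keep] <- (S / J)[keep]
      w0[keep] <- ((J - S) / J)[keep]
    } else {
      w1 <- S / J
      w0 <- (J - S) / J
    }
  }
  list(w1 = w1, w0 = w0)
}

#' Closed-form social-sampling update of popularity
#'
#' Marginal probability that the resample-until-accept chain settles on
#' belief 1 when companions are drawn from a previous generation with
#' popularity `p_prev`: `p L1 / (p L1 + (1 - p) L0)` — i.e. a Bayesian update
#' of the popularity-prior by the current evidence block. With
#' `acceptance = "matching"` the likelihoods are replaced by the evidence
#' fractions S/J and (J - S)/J. Consensus is absorbing: `p_prev` of 0 or 1 is
#' returned unchanged.
#'
#' @param p_prev previous generation's popularity of belief 1, in `[0, 1]`.
#' @inheritParams evidence_likelihood
#' @param acceptance `"bayes"` (likelihood acceptance) or `"matching"`.
#' @return updated probability in `[0, 1]`; vectorized over
#'   `p_prev`/`S`/`J`.
#' @export
#' @examples
#' social_update(0.5, S = 4, J = 4, theta1 = 0.6, theta0 = 0.3)
#' # 0.6^4 / (0.6^4 + 0.3^4)
social_update <- function(p_prev, S, J, theta1 = NULL, theta0 = NULL,
                          acceptance = c("bayes", "matching")) {
  acceptance <- match.arg(acceptance)
  ss_check(all(p_prev >= 0 & p_prev <= 1), "config_error",
           "p_prev must be in [0, 1]")
  w <- acceptance_weights(S, J, theta1, theta0, acceptance)
  num <- p_prev * w$w1
  den <- num + (1 - p_prev) * w$w0
  out <- ifelse(p_prev <= 0, 0, ifelse(p_prev >= 1, 1, num / den))
  bad <- den == 0 & p_prev > 0 & p_prev < 1
  if (any(bad)) {
    ss_error("degenerate_evidence_error",
             "evidence has zero acceptance weight under both beliefs")
  }
  out
}

#' Simulate social-sampling decisions
#'
#' Draws `n` independent decisions by the resample-until-accept rule against
#' a previous generation given by its decision vector: sample a companion
#' uniformly with replacement, accept their belief with the acceptance
#' probability of the evidence, repeat until acceptance or until
#' `max_resamples` companions have been tried (then keep the last sampled
#' companion's belief). The marginal P(decision = 1) equals
#' [social_update()] of the previous popularity whenever the cap is not hit.
#'
#' @param prev_decisions binary vector of the previous generation's decisions
#'   on this feature.
#' @inheritParams evidence_likelihood
#' @param n number of independent deciding agents to simulate.
#' @param acceptance `"bayes"` or `"matching"`.
#' @param max_resamples cap on companions sampled per decision.
#' @param norm_scale rescales acceptance probabilities; the marginal is
#'   invariant to it (up to longer loops).
#' @param first_companion optional integer vector (recycled to length `n`) of
#'   indices into `prev_decisions` forcing the first sampled companion; later
#'   rounds always sample uniformly. Used by the censored regime, where the
#'   recorded companion also fixes evidence visibility.
#' @return integer 0/1 vector of length `n` with attribute `"resamples"`
#'   counting companions sampled per decision.
#' @export
social_sampling_decision <- function(prev_decisions, S, J, theta1 = NULL,
                                     theta0 = NULL, n = 1,
                                     acceptance = c("bayes", "matching"),
                                     max_resamples = 1000, norm_scale = 1,
                                     first_companion = NULL) {
  acceptance <- match.arg(acceptance)
  n_prev <- length(prev_decisions)
  ss_check(n_prev >= 1 && is_binary(prev_decisions), "config_error",
           "prev_decisions must be a non-empty binary vector")
  ss_check(norm_scale > 0 && norm_scale <= 1, "config_error",
           "norm_scale must be in (0, 1]")
  w <- acceptance_weights(S, J, theta1, theta0, acceptance)
  m <- max(w$w1, w$w0)
  if (m == 0) {
    ss_error("degenerate_evidence_error",
             "evidence has zero acceptance weight under both beliefs")
  }
  a1 <- w$w1 / m * norm_scale
  a0 <- w$w0 / m * norm_scale

  comp <- if (is.null(first_companion)) {
    sample.int(n_prev, n, replace = TRUE)
  } else {
    rep_len(as.integer(first_companion), n)
  }
  cand <- prev_decisions[comp]
  resamples <- rep.int(1L, n)
  accepted <- runif(n) < ifelse(cand == 1, a1, a0)
  while (any(!accepted)) {
    idx <- which(!accepted)
    if (resamples[idx[1]] >= max_resamples) break # fallback: keep last sample
    redraw <- prev_decisions[sample.int(n_prev, length(idx), replace = TRUE)]
    cand[idx] <- redraw
    resamples[idx] <- resamples[idx] + 1L
    accepted[idx] <- runif(length(idx)) < ifelse(redraw == 1, a1, a0)
  }
  structure(as.integer(cand), resamples = resamples)
}

# posterior of belief 1 from a single block under a uniform prior
block_posterior <- function(S, J, theta1, theta0) {
  ideal_posterior(S, t = 1, J = J, theta1 = theta1, theta0 = theta0)
}

# probability that an asocial rule chooses 1, vectorized over S (and J)
asocial_prob <- function(model_id, S, J, theta1, theta0) {
  check_model_id(model_id)
  ss_check(model_id %in% ASOCIAL_MODELS, "config_error",
           paste(model_id, "is not an asocial rule"))
  check_counts(S, J)
  switch(model_id,
    nonsocial_matching = ifelse(J == 0, 0.5, S / ifelse(J == 0, 1, J)),
    nonsocial_bayes_matching = block_posterior(S, J, theta1, theta0),
    nonsocial_utility_max = {
      q <- block_posterior(S, J, theta1, theta0)
      ifelse(q > 0.5, 1, ifelse(q < 0.5, 0, 0.5))
    })
}

#' Simulate asocial decisions
#'
#' The three evidence-only rules: `nonsocial_matching` chooses 1 with
#' probability S/J (0.5 on an empty block); `nonsocial_bayes_matching`
#' probability-matches the single-block posterior under a uniform prior;
#' `nonsocial_utility_max` deterministically takes the posterior mode
#' (fair coin at exactly 0.5).
#'
#' @param model_id one of the three `nonsocial_*` ids.
#' @inheritParams evidence_likelihood
#' @param n number of independent decisions.
#' @return integer 0/1 vector of length `n`.
#' @export
asocial_decision <- function(model_id, S, J, theta1, theta0, n = 1) {
  p <- asocial_prob(model_id, S, J, theta1, theta0)
  rbinom(n, 1L, p)
}

#' One-step-ahead predicted popularity under each decision model
#'
#' The analytic expectation of the next generation's popularity given the
#' previous generation's observed popularity `p_prev` and the evidence block
#' the deciders see. Social-sampling models are a mixture: a fraction `rho`
#' follows the social closed form and `1 - rho` follows the like-for-like
#' asocial rule. In the censored regime the prediction averages over the
#' previous generation's designs: a fraction `p_prev` of companions chose the
#' feature (evidence visible; the first companion's positive belief is
#' accepted with probability A1, otherwise the chain falls back to the
#' closed-form marginal) and the rest censor it (social deciders copy the
#' companion's 0; asocial deciders face a flat likelihood, probability 0.5).
#'
#' @param model_id one of the six model ids.
#' @param p_prev previous generation's popularity.
#' @inheritParams evidence_likelihood
#' @param rho proportion of social decision making, in `[0, 1]`; applies to
#'   the two `social_sampling_*` models only.
#' @param censored logical; use the companion-averaged censored prediction.
#' @return predicted popularity in `[0, 1]`, vectorized over rows.
#' @export
predicted_popularity <- function(model_id, p_prev, S, J, theta1, theta0,
                                 rho = 1, censored = FALSE) {
  check_model_id(model_id)
  ss_check(all(rho >= 0 & rho <= 1), "config_error", "rho must be in [0, 1]")
  ss_check(all(p_prev >= 0 & p_prev <= 1), "config_error",
           "p_prev must be in [0, 1]")
  if (model_id == "naive_copy") return(rep_len(p_prev, max(length(p_prev), length(S))))

  if (model_id %in% ASOCIAL_MODELS) {
    param <- asocial_prob(model_id, S, J, theta1, theta0)
    if (!censored) return(rep_len(param, max(length(p_prev), length(param))))
    return(p_prev * param + (1 - p_prev) * 0.5)
  }

  acc <- if (model_id == "social_sampling_bayes") "bayes" else "matching"
  partner <- ASOCIAL_PARTNER[[model_id]]
  q <- social_update(p_prev, S, J, theta1, theta0, acceptance = acc)
  if (!censored) {
    asoc <- asocial_prob(partner, S, J, theta1, theta0)
    return(rho * q + (1 - rho) * asoc)
  }
  w <- acceptance_weights(S, J, theta1, theta0, acc)
  m <- pmax(w$w1, w$w0)
  if (any(m == 0)) {
    ss_error("degenerate_evidence_error",
             "evidence has zero acceptance weight under both beliefs")
  }
  a1 <- w$w1 / m
  social_pred <- p_prev * (a1 + (1 - a1) * q)
  asoc_cens <- p_prev * asocial_prob(partner, S, J, theta1, theta0) +
    (1 - p_prev) * 0.5
  rho * social_pred + (1 - rho) * asoc_cens
}
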