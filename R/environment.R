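# Hidden truths and generation-shared Bernoulli evidence.
#
# One trial has a binary feature vector x (the environment) and emission
# probabilities theta1 = P(y = 1 | x_i = 1), theta0 = P(y = 1 | x_i = 0)
# applied uniformly to all features. Each generation t observes one shared
# block of J Bernoulli outcomes per feature; S_t[i] counts the positive ones.

#' Describe a trial's hidden environment
#'
#' @param truth binary vector x of feature truths.
#' @param theta1 probability of a positive outcome when the feature is true.
#' @param theta0 probability of a positive outcome when the feature is false.
#' @return an object of class `feature_spec`.
#' @export
#' @examples
#' feature_spec(c(1, 0, 1), theta1 = 0.6, theta0 = 0.3)
feature_spec <- function(truth, theta1, theta0) {
  ss_check(length(truth) >= 1 && is_binary(truth),
           "config_error", "truth must be a non-empty binary vector")
  ss_check(is.numeric(theta1) && length(theta1) == 1 &&
           theta1 >= 0 && theta1 <= 1,
           "config_error", "theta1 must be a probability in [0, 1]")
  ss_check(is.numeric(theta0) && length(theta0) == 1 &&
           theta0 >= 0 && theta0 <= 1,
           "config_error", "theta0 must be a probability in [0, 1]")
  structure(
    list(n_features = length(truth), truth = as.integer(truth),
         theta1 = theta1, theta0 = theta0),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> F = %d, theta1 = %g, theta0 = %g\ntruth: %s\n",
              x$n_features, x$theta1, x$theta0,
              paste(x$truth, collapse = "")))
  invisible(x)
}

#' Sample a hidden truth vector
#'
#' Each feature is independently true with probability 0.5, drawn from R's
#' global RNG (seed it with [set.seed()] for reproducibility).
#'
#' @param n_features number of binary features F.
#' @return integer 0/1 vector of length `n_features`.
#' @export
sample_truth <- function(n_features) {
  ss_check(is.numeric(n_features) && length(n_features) == 1 &&
           n_features >= 1 && n_features == floor(n_features),
           "config_error", "n_features must be a positive integer")
  rbinom(n_features, 1L, 0.5)
}

#' Generate generation-shared evidence blocks
#'
#' Draws T blocks of J Bernoulli outcomes per feature: y ~ Bern(theta1) for
#' true features, Bern(theta0) for false ones, independent across features,
#' observations and generations. Every agent of one generation sees the same
#' block (evidence is perfectly correlated within a generation).
#'
#' @param spec a [feature_spec()].
#' @param J number of outcomes per feature per generation (may be 0).
#' @param T_gen number of generations (blocks) to draw.
#' @return a list of `T_gen` objects of class `evidence_block`, each with
#'   fields `generation` (0-based), `outcomes` (F x J 0/1 matrix) and
#'   `positive_counts` (length-F integer vector S_t).
#' @export
generate_evidence <- function(spec, J, T_gen) {
  ss_check(inherits(spec, "feature_spec"), "config_error",
           "spec must be a feature_spec")
  ss_check(is.numeric(J) && length(J) == 1 && J >= 0 && J == floor(J),
           "config_error", "J must be a non-negative integer")
  ss_check(is.numeric(T_gen) && length(T_gen) == 1 && T_gen >= 1 &&
           T_gen == floor(T_gen),
           "config_error", "T_gen must be a positive integer")
  f <- spec$n_features
  p <- ifelse(spec$truth == 1L, spec$theta1, spec$theta0)
  lapply(seq_len(T_gen) - 1L, function(g) {
    outcomes <- matrix(rbinom(f * J, 1L, rep(p, J)), nrow = f, ncol = J)
    structure(
      list(generation = g, outcomes = outcomes,
           positive_counts = as.integer(rowSums(outcomes))),
      class = "evidence_block"
    )
  })
}

#' Censor an evidence block through a companion's design
#'
#' In the censored regime evidence about a feature is visible to an agent only
#' if the sampled companion chose that feature; a censoring mask is therefore
#' the companion's decision vector. Unmasked features keep their (S, J);
#' masked features carry no evidence at all.
#'
#' @param block an `evidence_block`.
#' @param mask binary vector of length F; 1 = evidence visible.
#' @return list with integer vectors `S_eff` and `J_eff` of length F.
#' @export
censor_evidence <- function(block, mask) {
  ss_check(inherits(block, "evidence_block"), "config_error",
           "block must be an evidence_block")
  f <- length(block$positive_counts)
  ss_check(length(mask) == f && is_binary(mask), "shape_error",
           sprintf("mask must be a binary vector of length %d", f))
  keep <- as.integer(mask)
  list(S_eff = as.integer(block$positive_counts * keep),
       J_eff = as.integer(ncol(block$outcomes) * keep))
}
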