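# Accumulation metrics: ideal posterior, popularity, correlations,
# fixed-effects regression and the one-step-ahead predicted-popularity MSE
# used for model comparison.

#' Popularity of belief 1 in one generation
#'
#' The fraction of agents deciding 1, per feature: exact rationals on the
#' 1/N grid.
#'
#' @param decisions binary N x F matrix (agents x features) or a binary
#'   vector for a single feature.
#' @return numeric vector of length F (or length 1 for a vector input).
#' @export
popularity <- function(decisions) {
  if (is.matrix(decisions)) {
    ss_check(nrow(decisions) >= 1, "empty_generation_error",
             "decision matrix has no agents")
    ss_check(is_binary(decisions), "config_error", "decisions must be binary")
    return(colMeans(decisions))
  }
  ss_check(length(decisions) >= 1, "empty_generation_error",
           "decision vector is empty")
  ss_check(is_binary(decisions), "config_error", "decisions must be binary")
  mean(decisions)
}

#' Ideal Bayesian posterior given all evidence up to a generation
#'
#' Posterior probability that a feature is true under a uniform prior, given
#' the total positive evidence `S_cum` out of `t * J` Bernoulli outcomes
#' observed by the whole population through generation t:
#' `theta1^S (1-theta1)^(tJ-S) / [theta1^S (1-theta1)^(tJ-S) +
#' theta0^S (1-theta0)^(tJ-S)]`, computed in log space. The pair
#' `(S_cum, t J)` is the sufficient statistic; `S_cum / (t J)` is the
#' total-evidence fraction reported by the metrics pipeline.
#'
#' @param S_cum cumulative positive evidence, `0 <= S_cum <= t * J`.
#' @param t number of generations of evidence pooled.
#' @param J outcomes per generation.
#' @param theta1,theta0 emission probabilities.
#' @return posterior probability in `[0, 1]`; 0.5 when `t * J = 0` or
#'   `theta1 == theta0`. Vectorized over `S_cum` and `t`.
#' @export
#' @examples
#' ideal_posterior(3, t = 1, J = 4, theta1 = 0.6, theta0 = 0.3)
ideal_posterior <- function(S_cum, t, J, theta1, theta0) {
  n <- t * J
  ss_check(all(S_cum >= 0 & S_cum <= n), "domain_error",
           "S_cum must satisfy 0 <= S_cum <= t * J")
  ll1 <- xlogy(S_cum, theta1) + xlogy(n - S_cum, 1 - theta1)
  ll0 <- xlogy(S_cum, theta0) + xlogy(n - S_cum, 1 - theta0)
  m <- pmax(ll1, ll0)
  if (any(!is.finite(m))) {
    ss_error("degenerate_evidence_error",
             "evidence impossible under both hypotheses")
  }
  e1 <- exp(ll1 - m)
  e0 <- exp(ll0 - m)
  e1 / (e1 + e0)
}

#' Pearson correlation between two analysis columns
#'
#' @param rows data frame of analysis rows.
#' @param x_field,y_field column names.
#' @return list with `r`, `df` (n - 2), `statistic` (t) and `p_value`.
#' @export
correlate <- function(rows, x_field, y_field) {
  for (f in c(x_field, y_field)) {
    ss_check(f %in% names(rows), "schema_error",
             sprintf("missing column '%s'", f))
  }
  x <- rows[[x_field]]
  y <- rows[[y_field]]
  ss_check(length(x) >= 3, "undefined_correlation_error",
           "need at least 3 rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ss_error("undefined_correlation_error",
             "zero variance in one of the columns")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Fixed-effects regression of popularity on evidence
#'
#' OLS of popularity on the total-evidence fraction, the last-block evidence
#' fraction, and dummy-coded fixed effects for each grouping column (first
#' level as reference). Two-tailed t statistics on the residual degrees of
#' freedom.
#'
#' @param rows analysis rows (see [analysis_rows()]).
#' @param group_fields character vector of grouping columns, e.g.
#'   `"network"` or `c("network", "condition")`.
#' @return object of class `popularity_regression`: list with `coefficients`
#'   (data frame: term, estimate, t, p_value), `df_residual`, `n`, `fit`.
#' @export
regress_popularity <- function(rows, group_fields = "network") {
  needed <- c("popularity", "total_evidence_fraction",
              "last_evidence_fraction", group_fields)
  for (f in needed) {
    ss_check(f %in% names(rows), "schema_error",
             sprintf("missing column '%s'", f))
  }
  dat <- rows[, needed, drop = FALSE]
  for (f in group_fields) dat[[f]] <- factor(dat[[f]])
  group_fields <- group_fields[vapply(group_fields,
                                      function(f) nlevels(dat[[f]]) > 1,
                                      logical(1))]
  fml <- stats::as.formula(paste(
    "popularity ~ total_evidence_fraction + last_evidence_fraction",
    if (length(group_fields)) paste("+", paste(group_fields, collapse = " + "))
    else ""))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    ss_error("singular_design_error", "design matrix is rank deficient")
  }
  sm <- summary(fit)$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(sm),
                                   estimate = sm[, 1], se = sm[, 2],
                                   t = sm[, 3], p_value = sm[, 4],
                                   row.names = NULL),
         df_residual = fit$df.residual, n = nrow(dat), fit = fit),
    class = "popularity_regression"
  )
}

#' @export
print.popularity_regression <- function(x, ...) {
  cat(sprintf("<popularity_regression> n = %d, residual df = %d\n",
              x$n, x$df_residual))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Compare decision models by one-step-ahead prediction MSE
#'
#' For each model, the mean over analysis rows of the squared difference
#' between the model's predicted popularity (from the *observed* previous
#' popularity and the evidence the deciders saw, not from the model's own
#' rollout) and the observed popularity. Rows must be social generations
#' (generation >= 1) carrying `p_prev`.
#'
#' @param rows analysis rows with columns `p_prev`, `popularity`, `S_last`,
#'   `J`, `theta1`, `theta0` (and optionally `censored`).
#' @param models character vector of model ids to score.
#' @param rho social proportion used by the two social-sampling models.
#' @param censored logical; if `NULL` (default) taken from the rows'
#'   `censored` column (FALSE when absent).
#' @return object of class `model_comparison`: data frame with columns
#'   `model`, `mse`, `rank`, sorted ascending by MSE.
#' @export
model_mse <- function(rows, models = MODEL_IDS, rho = 1, censored = NULL) {
  needed <- c("p_prev", "popularity", "S_last", "J", "theta1", "theta0")
  for (f in needed) {
    ss_check(f %in% names(rows), "schema_error",
             sprintf("missing column '%s'", f))
  }
  ss_check(!anyNA(rows$p_prev), "schema_error",
           "p_prev has missing values (generation-0 rows must be dropped)")
  cens <- censored %||% (if ("censored" %in% names(rows))
    as.logical(rows$censored) else FALSE)
  mses <- vapply(models, function(m) {
    pred <- numeric(nrow(rows))
    for (cz in unique(cens)) {
      sel <- cens == cz
      pred[sel] <- predicted_popularity(
        m, rows$p_prev[sel], rows$S_last[sel], rows$J[sel],
        rows$theta1[sel], rows$theta0[sel], rho = rho, censored = cz)
    }
    mean((pred - rows$popularity)^2)
  }, numeric(1))
  out <- data.frame(model = models, mse = unname(mses))
  out <- out[order(out$mse), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> one-step-ahead predicted-popularity MSE\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
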