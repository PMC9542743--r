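# Independent oracles and small fixtures used across the suite.

# Brute-force two-hypothesis Bayes: enumerate every binary evidence sequence
# of length n with S positive outcomes and sum the sequence likelihoods under
# each hypothesis (uniform prior). Independent of the package's log-space
# sufficient-statistic shortcut.
enum_posterior <- function(S, n, theta1, theta0) {
  if (n == 0) return(0.5)
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
  keep <- rowSums(seqs) == S
  lik <- function(th) {
    sum(apply(seqs[keep, , drop = FALSE], 1,
              function(y) prod(ifelse(y == 1, th, 1 - th))))
  }
  l1 <- lik(theta1)
  l0 <- lik(theta0)
  l1 / (l1 + l0)
}

# Truncated geometric-series enumeration of the resample-until-accept chain:
# P(accept belief 1 within K rounds) / P(accept within K rounds).
chain_enum <- function(p, a1, a0, K = 200) {
  r <- p * a1 + (1 - p) * a0
  acc1 <- sum((1 - r)^(0:(K - 1))) * p * a1
  acc <- sum((1 - r)^(0:(K - 1))) * r
  acc1 / acc
}

# binary vector of length N with exact popularity p
prev_vec <- function(p, N = 20) {
  k <- round(p * N)
  stopifnot(abs(k - p * N) < 1e-9)
  rep(c(1L, 0L), c(k, N - k))
}

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

mc_se <- function(q, n) sqrt(q * (1 - q) / n)
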