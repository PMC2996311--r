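# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Brute-force KS distance: scan every sample point and both sides of the
# empirical step explicitly.
brute_force_ks <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  d <- 0
  for (i in seq_len(n)) {
    Fi <- cdf(x[i])
    d <- max(d, abs(i / n - Fi), abs((i - 1) / n - Fi))
  }
  d
}

# Numeric maximization of the continuous power-law log-likelihood.
numeric_alpha_mle <- function(x, x_min = 1) {
  nll <- function(alpha) {
    -sum(log(alpha - 1) + (alpha - 1) * log(x_min) - alpha * log(x))
  }
  stats::optimize(nll, c(1 + 1e-8, 60), tol = 1e-10)$minimum
}

# Textbook samplers for the distributional cross-checks: structurally
# different algorithms from the package generators.
oracle_pareto <- function(n, alpha, x_min = 1) {
  # Pareto as an exponentiated exponential
  x_min * exp(stats::rexp(n, rate = alpha - 1))
}

oracle_truncated_exp <- function(n, tau) {
  # memorylessness: left-truncation at 1 is a unit shift
  1 + stats::rexp(n, rate = 1 / tau)
}

# binomial standard error of a proportion estimated from n trials
prop_se <- function(p, n) sqrt(pmax(p * (1 - p), 0.25 / n) / n)
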