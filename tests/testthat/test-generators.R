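test_that("power-law draws follow the inverse CDF and the truncation rule", {
  s <- draw_power_law(1e6, alpha = 3, x_min = 1, seed = 101)
  expect_s3_class(s, "bout_sample")
  expect_length(s, 1e6)
  expect_gte(min(s), 1)
  # analytic moment of the Pareto: E ln(x/x_min) = 1/(alpha - 1)
  expect_lt(abs(mean(log(s)) - 0.5), 0.005)
  # inverse-CDF boundary: u = 0 maps to x_min exactly
  expect_equal(plaw_quantile(0, power_law_model(3, x_min = 2)), 2)
  # invalid exponent
  expect_error(draw_power_law(10, alpha = 1), "invalid parameter")
})

test_that("exponential-mixture draws meet quotas exactly and are truncated", {
  spec <- mixture_spec(tau = c(1, 15), n_draws = c(30, 10))
  s <- draw_exponential_mixture(spec, seed = 7)
  expect_length(s, 40)
  expect_gte(min(s), 1)
  expect_equal(as.vector(table(attr(s, "component"))), c(30, 10))

  # left-truncated exponential mean is 1 + tau by memorylessness
  s1 <- draw_exponential_mixture(mixture_spec(5, 1e6), seed = 8)
  expect_lt(abs(mean(s1) - 6), 0.02)

  # degenerate quota: zero draws from one component
  s0 <- draw_exponential_mixture(mixture_spec(c(1, 15), c(40, 0)), seed = 9)
  expect_length(s0, 40)

  # zero-quota component consumes no randomness: degenerate two-component
  # run equals the mono-exponential run under the same seed
  a <- draw_exponential_mixture(mixture_spec(c(1, 15), c(0, 25)), seed = 11)
  b <- draw_exponential_mixture(mixture_spec(15, 25), seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))

  # untruncated mode for the alternative reading
  su <- draw_exponential_mixture(mixture_spec(0.3, 2000), seed = 12,
                                 truncate_at_one = FALSE)
  expect_lt(min(su), 1)
})

test_that("generators are byte-reproducible given a seed", {
  for (draw in list(
    function() draw_power_law(500, 3, seed = 42),
    function() draw_exponential_mixture(mixture_spec(c(1, 6, 60), c(50, 30, 20)), seed = 42),
    function() sample_from_fitted(exp_mixture_model(c(10, 1), c(1, 12)), 500, seed = 42)
  )) {
    expect_identical(as.numeric(draw()), as.numeric(draw()))
  }
  h1 <- simulate_markov_hypnogram(markov_spec(0.9, 0.8, 200), seed = 42)
  h2 <- simulate_markov_hypnogram(markov_spec(0.9, 0.8, 200), seed = 42)
  expect_identical(as.numeric(h1$sleep_bouts), as.numeric(h2$sleep_bouts))
})

test_that("Markov hypnogram bouts are geometric with the expected mean", {
  spec <- markov_spec(p_stay_sleep = 0.9, p_stay_wake = 0.9, n_bouts = 4000)
  h <- simulate_markov_hypnogram(spec, seed = 5)
  expect_length(h$sleep_bouts, 4000)
  expect_length(h$wake_bouts, 4000)
  expect_gte(min(h$sleep_bouts), 1)
  # geometric mean 1/(1 - p) = 10, SE = sqrt((1-p)... ) ~ sd/sqrt(n)
  m <- mean(h$sleep_bouts)
  se <- stats::sd(as.numeric(h$sleep_bouts)) / sqrt(4000)
  expect_lt(abs(m - 10), 3 * se)
  # near-absorbing exit: nearly all bouts length 1
  h2 <- simulate_markov_hypnogram(markov_spec(0.01, 0.5, 500), seed = 6)
  expect_gt(mean(as.numeric(h2$sleep_bouts) == 1), 0.95)
})

test_that("sample_from_fitted matches the fitted model's law", {
  # mono-exponential model: mean 1 + tau
  s <- sample_from_fitted(exp_mixture_model(1, 4), 1e6, seed = 21)
  expect_lt(abs(mean(s) - 5), 0.02)
  # power-law model: same distribution as draw_power_law (same inverse CDF)
  a <- sample_from_fitted(power_law_model(3), 1000, seed = 22)
  b <- draw_power_law(1000, 3, seed = 22)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("draws match independent textbook implementations (two-sample KS)", {
  n <- 1e5
  set.seed(314)
  ref_pareto <- oracle_pareto(n, 3)
  ref_exp <- oracle_truncated_exp(n, 5)
  ref_geom <- 1 + stats::rgeom(2000, prob = 0.1)
  s_pareto <- draw_power_law(n, 3, seed = 315)
  s_exp <- draw_exponential_mixture(mixture_spec(5, n), seed = 316)
  h <- simulate_markov_hypnogram(markov_spec(0.9, 0.9, 2000), seed = 317)
  expect_gt(suppressWarnings(stats::ks.test(as.numeric(s_pareto), ref_pareto))$p.value, 0.001)
  expect_gt(suppressWarnings(stats::ks.test(as.numeric(s_exp), ref_exp))$p.value, 0.001)
  # discrete bout lengths: compare via chi-squared on the first 20 lengths
  tb <- table(factor(as.numeric(h$sleep_bouts), levels = 1:20))
  pr <- stats::dgeom(0:19, 0.1); pr <- pr / sum(pr)
  expect_gt(suppressWarnings(stats::chisq.test(tb, p = pr))$p.value, 0.001)
})

test_that("bout_sample rejects sub-epoch durations", {
  expect_error(bout_sample(c(1.5, 0.4)), "truncation")
  expect_error(bout_sample(numeric(0)), "at least one")
})
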