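test_that("KS distance matches trivial cases and the brute-force oracle", {
  m <- power_law_model(3)
  # single observation at the model median
  expect_equal(ks_distance(plaw_quantile(0.5, m), m), 0.5, tolerance = 1e-12)
  # best-case spacing: points at quantiles (i - 0.5)/n give d = 0.5/n
  n <- 20
  x <- plaw_quantile((seq_len(n) - 0.5) / n, m)
  expect_equal(ks_distance(x, m), 0.5 / n, tolerance = 1e-12)
  # brute-force oracle over random cases, both model families
  set.seed(7)
  for (i in 1:500) {
    x <- oracle_pareto(sample(2:40, 1), 3)
    expect_equal(ks_distance(x, m), brute_force_ks(x, function(q) plaw_cdf(q, m)),
                 tolerance = 1e-12)
  }
  me <- exp_mixture_model(c(10, 1), c(1, 8))
  cdf <- normalize_to_pdf(me)$cdf
  for (i in 1:500) {
    x <- oracle_truncated_exp(sample(2:40, 1), 4)
    expect_equal(ks_distance(x, me), brute_force_ks(x, cdf), tolerance = 1e-12)
  }
})

test_that("bootstrap p-values have 1/n_ref granularity and the stated tie rule", {
  s <- draw_power_law(60, 3, seed = 61)
  res <- ks_bootstrap_p(s, "powerlaw", n_ref = 40, seed = 62)
  expect_true(res$p_value %in% ((0:40) / 40))
  expect_identical(res$reject, res$p_value < 0.05)
  expect_length(res$d_s, 40)
  expect_true(all(res$d_s >= 0))
  expect_true(res$d_o >= 0 && res$d_o <= 1)
  # p counts d_s >= d_o, so d_o below every d_s gives p = 1
  expect_equal(mean(res$d_s >= min(res$d_s) - 1e-9), 1)
})

test_that("bootstrap is reproducible and propagates fit failure", {
  s <- draw_power_law(50, 3, seed = 63)
  a <- ks_bootstrap_p(s, "powerlaw", n_ref = 30, seed = 64)
  b <- ks_bootstrap_p(s, "powerlaw", n_ref = 30, seed = 64)
  expect_identical(a$d_s, b$d_s)
  expect_identical(a$p_value, b$p_value)
  # a sample too sparse for a 3-exponential fit propagates non-convergence
  tiny <- bout_sample(c(1.1, 1.2, 1.4, 2.2))
  expect_s3_class(ks_bootstrap_p(tiny, "exp3", n_ref = 5, seed = 65),
                  "boutlaw_nonconvergence")
})

test_that("mimicry probability: degenerate edges match mono-exponential runs", {
  two_comp <- mixture_spec(c(1, 15), c(0, 30))
  mono <- mixture_spec(15, 30)
  a <- mimicry_probability(two_comp, "powerlaw", iterations = 12, n_ref = 30, seed = 71)
  b <- mimicry_probability(mono, "powerlaw", iterations = 12, n_ref = 30, seed = 71)
  expect_identical(a$p_values, b$p_values)
  expect_identical(a$fraction_not_rejected, b$fraction_not_rejected)
})

test_that("mimicry probability bookkeeping is consistent", {
  gen <- mixture_spec(c(1, 15), c(30, 10))
  r <- mimicry_probability(gen, "powerlaw", iterations = 10, n_ref = 20, seed = 72)
  expect_gte(r$fraction_not_rejected, 0)
  expect_lte(r$fraction_not_rejected, 1)
  expect_lte(r$n_converged, r$iterations)
  expect_length(r$p_values, 10)
  expect_lte(r$fraction_all_iterations, r$fraction_not_rejected + 1e-12)
  # sample-size monotonicity of mimicry for a fixed cell, common seeds
  lo <- mimicry_probability(mixture_spec(c(1, 15), c(30, 10)), "powerlaw",
                            iterations = 30, n_ref = 50, seed = 73)
  hi <- mimicry_probability(mixture_spec(c(1, 15), c(480, 160)), "powerlaw",
                            iterations = 30, n_ref = 50, seed = 73)
  tol <- 3 * sqrt(prop_se(lo$fraction_not_rejected, 30)^2 +
                    prop_se(hi$fraction_not_rejected, 30)^2)
  expect_lte(hi$fraction_not_rejected, lo$fraction_not_rejected + tol)
})
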