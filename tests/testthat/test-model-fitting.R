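test_that("floor binning is exact and conserves counts", {
  h <- bin_histogram(bout_sample(c(1.2, 1.9, 3.0, 3.7)))
  expect_equal(h$bin_start, c(1, 3))
  expect_equal(h$counts, c(2, 2))
  expect_equal(h$total, 4)
  # conservation over random samples
  for (seed in 1:5) {
    s <- draw_power_law(200, 2.5, seed = seed)
    expect_equal(sum(bin_histogram(s)$counts), 200)
  }
  expect_error(bin_histogram(numeric(0)), "empty")
})

test_that("binned truncated-exponential counts decay geometrically", {
  s <- draw_exponential_mixture(mixture_spec(5, 1e5), seed = 31)
  h <- bin_histogram(s)
  r <- exp(-1 / 5)
  for (b in 1:10) {
    c0 <- h$counts[match(b, h$bin_start)]
    c1 <- h$counts[match(b + 1, h$bin_start)]
    # adjacent bin counts are independent Poisson-like, so
    # var(c1 - r c0) ~ E c1 + r^2 E c0
    se <- sqrt(c1 + r^2 * c0)
    expect_lt(abs(c1 - c0 * r), 3 * se + 1)
  }
})

test_that("power-law MLE equals the closed form and the numeric oracle", {
  m <- fit_power_law_mle(bout_sample(c(1, 2, 4, 8)))
  expect_equal(m$alpha, 1 + 4 / log(64), tolerance = 1e-12)
  # closed form vs direct likelihood maximization on 100 random samples
  set.seed(99)
  for (i in 1:100) {
    x <- oracle_pareto(50, runif(1, 1.5, 4))
    expect_equal(fit_power_law_mle(x)$alpha, numeric_alpha_mle(x),
                 tolerance = 1e-6)
  }
  # degenerate sample
  expect_error(fit_power_law_mle(rep(1, 10)), "degenerate")
})

test_that("power-law MLE recovers alpha at large n", {
  s <- draw_power_law(1e5, 3, seed = 41)
  expect_lt(abs(fit_power_law_mle(s)$alpha - 3), 0.02)
})

test_that("exponential NLS recovers noiseless and synthetic mixtures", {
  # noiseless mono-exponential: exact recovery
  counts <- 100 * exp(-((1:50) + 0.5) / 4)
  h <- structure(list(bin_start = 1:50, counts = counts, total = sum(counts)),
                 class = "duration_histogram")
  f <- fit_exponentials_nls(h, 1, seed = 1)
  expect_true(is_converged(f))
  expect_equal(f$taus, 4, tolerance = 1e-4)
  expect_equal(f$amplitudes, 100, tolerance = 1e-4)

  # two-component synthetic mixture: taus within 10% after canonical ordering
  s <- draw_exponential_mixture(mixture_spec(c(1, 10), c(5e4, 5e4)), seed = 2)
  f2 <- fit_exponentials_nls(bin_histogram(s), 2, seed = 3)
  expect_true(is_converged(f2))
  expect_lt(abs(f2$taus[1] - 1), 0.1)
  expect_lt(abs(f2$taus[2] - 10), 1)

  # idempotence: refitting a model's own noiseless predictions returns it
  m <- exp_mixture_model(c(120, 8), c(1.3, 11))
  xs <- (1:60) + 0.5
  h2 <- structure(list(bin_start = 1:60, counts = predict(m, xs), total = 1),
                  class = "duration_histogram")
  f3 <- fit_exponentials_nls(h2, 2, seed = 4)
  expect_true(is_converged(f3))
  expect_equal(c(f3$amplitudes, f3$taus), c(m$amplitudes, m$taus),
               tolerance = 1e-6)
})

test_that("constraint screen: returned models always have positive parameters", {
  n_models <- 0
  for (seed in 1:40) {
    s <- draw_power_law(40, 3, seed = seed)
    for (k in 1:3) {
      f <- fit_exponentials_nls(bin_histogram(s), k, seed = 1000 + seed)
      if (is_converged(f)) {
        n_models <- n_models + 1
        expect_true(all(f$amplitudes > 0))
        expect_true(all(f$taus > 0))
        expect_true(!is.unsorted(f$taus))
      } else {
        expect_s3_class(f, "boutlaw_nonconvergence")
        expect_true(f$reason %in% c("optimizer-failure", "constraint-violation"))
      }
    }
  }
  expect_gt(n_models, 20) # most k=1 fits converge
  expect_error(fit_exponentials_nls(bin_histogram(1:5), 4), "invalid parameter")
})

test_that("normalize_to_pdf gives a proper density with closed-form CDF", {
  d <- normalize_to_pdf(exp_mixture_model(1, 1))
  expect_equal(d$Z, exp(-1), tolerance = 1e-12)
  expect_equal(d$cdf(2), 1 - exp(-1), tolerance = 1e-12)
  # CDF axioms and quadrature for a three-component model with a slow tau
  m <- exp_mixture_model(c(50, 5, 0.4), c(1, 6, 60))
  d3 <- normalize_to_pdf(m)
  expect_equal(d3$cdf(1), 0)
  q <- seq(1, 5000, length.out = 400)
  expect_true(!is.unsorted(d3$cdf(q)))
  expect_lt(abs(d3$cdf(1e5) - 1), 1e-10)
  quad <- stats::integrate(d3$pdf, 1, 1e4, rel.tol = 1e-9)$value
  expect_lt(abs(quad - 1), 1e-6)
  expect_equal(sum(d3$weights), 1, tolerance = 1e-12)
})

test_that("log-log OLS is exact on exact power-law counts and guards input", {
  xs <- (1:20) + 0.5
  h <- structure(list(bin_start = 1:20, counts = 5000 * xs^(-3), total = 1),
                 class = "duration_histogram")
  o <- fit_power_law_ols(h)
  expect_equal(o$slope, -3, tolerance = 1e-10)
  expect_equal(o$r_squared, 1, tolerance = 1e-10)
  expect_equal(o$n_bins_used, 20)
  h2 <- structure(list(bin_start = 1:2, counts = c(3, 1), total = 4),
                  class = "duration_histogram")
  expect_error(fit_power_law_ols(h2), "at least 3")
})

test_that("OLS R-squared separates straight from curved log-log decays", {
  # slow mono-exponential decays show log-log curvature; power-law samples
  # are straighter on average (single seeds can overlap, so compare means)
  r2_exp <- sapply(1:5, function(i) {
    s <- draw_exponential_mixture(mixture_spec(20, 1e4), seed = 50 + i)
    fit_power_law_ols(bin_histogram(s))$r_squared
  })
  r2_pl <- sapply(1:5, function(i) {
    p <- draw_power_law(1e4, 3, seed = 60 + i)
    fit_power_law_ols(bin_histogram(p))$r_squared
  })
  expect_gt(mean(r2_pl), mean(r2_exp))
})
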