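test_that("largest-remainder quotas are exact for the published configurations", {
  expect_equal(allocate_quotas(c(0.474, 0.342, 0.184), 38000),
               c(18012L, 12996L, 6992L))
  expect_equal(allocate_quotas(c(4, 1, 0.5), 640), c(466L, 116L, 58L))
  # property: quotas always sum to n
  set.seed(3)
  for (i in 1:50) {
    w <- runif(3)
    n <- sample(10:1000, 1)
    q <- allocate_quotas(w, n)
    expect_equal(sum(q), n)
    expect_true(all(q >= 0))
  }
  expect_error(allocate_quotas(c(0, 0), 10), "not all zero")
})

test_that("the three-exponential mimic demo reproduces its published construction", {
  d <- fig2_demo(seed = 90)
  expect_equal(d$component_totals, c(18012L, 12996L, 6992L))
  expect_equal(d$histogram$total, 38000)
  expect_equal(sum(vapply(d$component_histograms, function(h) h$total, 0)), 38000)
  # chosen to appear linear on the log-log plot
  expect_gt(d$ols_fit$r_squared, 0.9)
})

test_that("two-exp sweep emits a complete long-format grid with bounded fractions", {
  sw <- run_two_exp_sweep(n_values = 40, tau2_grid = c(5, 20),
                          proportion_grid = c(0, 0.5, 1),
                          iterations = 4, n_ref = 10, seed = 91)
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$fraction_not_rejected >= 0 & sw$fraction_not_rejected <= 1,
                  na.rm = TRUE))
  expect_equal(sw$n_fast + sw$n_slow, rep(40L, 6))
  # determinism: same seed, bit-identical results
  sw2 <- run_two_exp_sweep(n_values = 40, tau2_grid = c(5, 20),
                           proportion_grid = c(0, 0.5, 1),
                           iterations = 4, n_ref = 10, seed = 91)
  expect_identical(sw, sw2)
})

test_that("interrupted sweeps resume from per-cell checkpoints without changes", {
  cp <- file.path(tempdir(), "sweepcp")
  unlink(cp, recursive = TRUE)
  sw <- run_two_exp_sweep(n_values = 40, tau2_grid = 10, proportion_grid = c(0.3, 0.6),
                          iterations = 3, n_ref = 10, seed = 92, checkpoint_dir = cp)
  files <- list.files(cp)
  expect_length(files, 2)
  # tamper-proof resume: remove one checkpoint, rerun, results identical
  unlink(file.path(cp, files[1]))
  sw2 <- run_two_exp_sweep(n_values = 40, tau2_grid = 10, proportion_grid = c(0.3, 0.6),
                           iterations = 3, n_ref = 10, seed = 92, checkpoint_dir = cp)
  expect_equal(sw$fraction_not_rejected, sw2$fraction_not_rejected)
  unlink(cp, recursive = TRUE)
})

test_that("three-exp tau sweep skips the tau2 > tau3 half and keeps 1:1:1 quotas", {
  sw <- run_three_exp_tau_sweep(tau2_grid = c(2, 20), tau3_grid = c(5, 10),
                                n_values = 39, iterations = 3, n_ref = 10, seed = 93)
  expect_true(all(sw$skipped[sw$tau2 > sw$tau3]))
  expect_true(all(is.na(sw$fraction_not_rejected[sw$skipped])))
  expect_true(all(!is.na(sw$fraction_not_rejected[!sw$skipped])))
  expect_error(run_three_exp_tau_sweep(n_values = 40, iterations = 1, n_ref = 5),
               "divisible by 3")
})

test_that("three-exp proportion sweep maps ratios to exact quotas", {
  sw <- run_three_exp_proportion_sweep(ratio12_grid = c(1, 4), ratio23_grid = 2,
                                       n_values = 40, iterations = 3, n_ref = 10,
                                       seed = 94)
  expect_equal(sw$n1 + sw$n2 + sw$n3, rep(40L, 2))
  # ratio12 = 4, ratio23 = 2 -> weights (4, 1, 0.5)
  row <- sw[sw$ratio12 == 4, ]
  expect_equal(c(row$n1, row$n2, row$n3), allocate_quotas(c(4, 1, 0.5), 40))
})

test_that("rejection table has both criteria with exact criterion-2 denominators", {
  tb <- run_table1(n_values = 40, k_values = 1:3, iterations = 4, n_ref = 10,
                   seed = 95, max_attempts_factor = 30)
  expect_s3_class(tb, "table1_result")
  expect_setequal(unique(tb$criterion), c("converged_subset", "all_converged"))
  c2 <- tb[tb$criterion == "all_converged", ]
  expect_equal(c2$n_converged, rep(4L, 3))
  expect_true(all(tb$fraction_not_rejected >= 0 & tb$fraction_not_rejected <= 1,
                  na.rm = TRUE))
  c1 <- tb[tb$criterion == "converged_subset", ]
  expect_true(all(c1$n_converged <= c1$iterations))
})

test_that("the Vuong experiment driver reports both verdict conventions", {
  v <- run_vuong_experiment(replicates = 6, n = 160, seed = 96)
  expect_equal(v$quotas, allocate_quotas(c(4, 1, 0.5), 160))
  expect_gte(v$n_favor_powerlaw_sign, v$n_favor_powerlaw_significant)
  expect_lte(v$fraction_sign, 1)
  expect_gte(v$fraction_sign, 0)
})

test_that("OLS sweep records mean R-squared over the same cells", {
  sw <- run_two_exp_ols_sweep(n_values = 40, tau2_grid = 15, proportion_grid = c(0.25, 0.75),
                              iterations = 5, seed = 97)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$mean_r_squared > 0 & sw$mean_r_squared <= 1, na.rm = TRUE))
  expect_true(all(sw$n_fits <= 5))
})
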