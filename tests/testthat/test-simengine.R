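test_that("one replication yields 13 records, bit-identically reproducible", {
  cfg <- scenario_config(0.6, 1.5, n_reps = 10, seed = 71)
  recs <- run_replication(cfg, 3)
  expect_length(recs, 13)
  expect_equal(recs[[1]]$method, "uncorrected")
  tab <- table(vapply(recs, `[[`, character(1), "method"))
  expect_equal(as.vector(tab[c("ivs_restricted", "standard_rc",
                               "validation_rc", "efficient_rc")]),
               rep(3L, 4))
  expect_identical(recs, run_replication(cfg, 3))
  # different replication index gives different draws
  expect_false(identical(recs[[1]]$beta_hat,
                         run_replication(cfg, 4)[[1]]$beta_hat))
})

test_that("a validation fraction of one makes all strategies coincide", {
  cfg <- scenario_config(0.6, 1.5, val_fraction = 1, n_reps = 5, seed = 72)
  recs <- run_replication(cfg, 1)
  ivs <- recs[vapply(recs, `[[`, character(1), "method") == "ivs_restricted"]
  betas <- vapply(ivs, `[[`, numeric(1), "beta_hat")
  expect_equal(betas[2], betas[1])
  expect_equal(betas[3], betas[1])
})

test_that("performance summary matches hand-worked arithmetic", {
  # estimates (0.1, 0.2, 0.3) against truth 0.2, huge SEs so all CIs cover
  s <- summarize_performance(c(0.1, 0.2, 0.3), rep(10, 3), truth = 0.2)
  expect_equal(s$bias, 0)
  expect_equal(s$mse, 0.02 / 3)
  expect_equal(s$emp_se, 0.1)
  expect_equal(s$coverage, 1)
  expect_equal(s$mcse_bias, 0.1 / sqrt(3))
  # all estimates exact and covering
  s2 <- summarize_performance(rep(0.2, 5), rep(1, 5), truth = 0.2)
  expect_equal(s2$bias, 0)
  expect_equal(s2$mse, 0)
  expect_equal(s2$coverage, 1)
  # binomial MCSE of coverage at its nominal level
  expect_equal(sqrt(0.95 * 0.05 / 5000), 0.0030822, tolerance = 1e-4)
  k <- 5000
  cov95 <- c(rep(0.2, 4750), rep(10, 250))  # 95% of CIs cover
  s3 <- summarize_performance(cov95, rep(0.001, k), truth = 0.2)
  expect_equal(s3$coverage, 0.95)
  expect_equal(s3$mcse_coverage, sqrt(0.95 * 0.05 / k))
  expect_error(summarize_performance(0.2, 1, 0.2), "at least 2")
})

test_that("non-converged replications are dropped and counted", {
  b <- c(0.1, 0.2, NA, 0.3)
  s <- summarize_performance(b, c(1, 1, NA, 1), truth = 0.2)
  expect_equal(s$n_reps_used, 3L)
  expect_equal(s$bias, 0)
})

test_that("MSE decomposes into squared bias plus scaled empirical variance", {
  cfg <- scenario_config(0.4, 3, n_reps = 50, seed = 73)
  res <- run_scenario(cfg)
  expect_equal(nrow(res), 13)
  K <- res$n_reps_used
  expect_true(all(abs(res$mse - (res$bias^2 + res$emp_se^2 * (K - 1) / K))
                  < 1e-12))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))
  expect_true(all(res$mcse_bias >= 0 & res$mcse_mse >= 0 &
                    res$mcse_coverage >= 0))
})

test_that("Monte Carlo standard errors shrink like one over root K", {
  cfg1 <- scenario_config(0.6, 0.1, n_reps = 500, seed = 74)
  cfg2 <- scenario_config(0.6, 0.1, n_reps = 1000, seed = 74)
  r1 <- run_scenario(cfg1)
  r2 <- run_scenario(cfg2)
  ratio <- r1$mcse_bias / r2$mcse_bias
  expect_true(all(abs(ratio - sqrt(2)) < 0.1 * sqrt(2)))
})

test_that("grid runs stack scenarios and tolerate a failing one", {
  cfgs <- list(scenario_config(0.6, 1.5, n_reps = 20, seed = 75),
               scenario_config(0.8, 0.1, n_reps = 20, seed = 75))
  tab <- run_grid(cfgs)
  expect_equal(nrow(tab), 26)
  expect_true(all(tab$n_reps_used <= 20))
  # identical master seed, different worker counts: identical tables
  tab2 <- run_grid(cfgs, workers = 2L)
  expect_equal(tab, tab2)
  # a scenario whose cohort size cannot support the models fails alone
  cfgs_bad <- c(cfgs, list(scenario_config(0.4, 1, n = 4, n_reps = 20,
                                           seed = 75)))
  expect_warning(tab3 <- run_grid(cfgs_bad), "failed")
  expect_equal(nrow(tab3), 26)
})

test_that("MSE reduction averages the per-scenario percentage decreases", {
  toy <- data.frame(
    r2_target = rep(c(0.2, 0.4), each = 2), skewness = 1, linear = TRUE,
    differential = FALSE, val_fraction = 0.4,
    strategy = rep(c("extremes", "random"), 2),
    method = "validation_rc",
    mse = c(0.8, 1.0, 0.9, 1.0))
  red <- mse_reduction(toy, "extremes", "validation_rc")
  expect_equal(red$average, 15)
  expect_equal(sort(red$per_scenario$pct_decrease), c(10, 20))
  # self-comparison is identically zero
  red0 <- mse_reduction(toy, "random", "validation_rc")
  expect_equal(red0$average, 0)
  expect_error(mse_reduction(toy, "stratified", "validation_rc"), "no rows")
  # missing baseline scenario detected
  toy_miss <- toy[-2, ]
  expect_error(mse_reduction(toy_miss, "extremes", "validation_rc"),
               "missing")
})

test_that("nested-loop export orders linearity, then skewness, then R^2", {
  tab <- expand.grid(r2_target = c(0.4, 0.2), skewness = c(3, 0.1),
                     linear = c(FALSE, TRUE), differential = FALSE,
                     val_fraction = 0.4, strategy = "random",
                     method = "uncorrected", mse = 1)
  out <- nested_loop_export(tab)
  expect_true(all(diff(out$scenario_order) >= 0))
  expect_equal(out$linear[1], TRUE)   # linear block first
  expect_equal(out$r2_target[1], 0.2) # R^2 innermost, increasing
  expect_equal(max(out$scenario_order), 8)
})
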