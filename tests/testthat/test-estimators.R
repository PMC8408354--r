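test_that("fit_linear agrees with lm's coefficients and covariance", {
  set.seed(14)
  X <- cbind(1, rnorm(40), rnorm(40), rnorm(40))
  y <- drop(X %*% c(1, 0.5, -0.2, 0)) + rnorm(40)
  f <- fit_linear(y, X)
  ref <- lm(y ~ X[, 2] + X[, 3] + X[, 4])
  expect_equal(unname(f$coef), unname(coef(ref)))
  expect_equal(unname(f$cov), unname(vcov(ref)), tolerance = 1e-10)
  expect_true(f$converged)
  # exact linear outcome: zero residual variance, exact coefficients
  f0 <- fit_linear(drop(X %*% c(2, 1, 1, 1)), X)
  expect_equal(f0$sigma2, 0, tolerance = 1e-20)
  expect_equal(unname(f0$coef), c(2, 1, 1, 1))
  # permutation invariance
  pi <- sample(40)
  expect_equal(fit_linear(y[pi], X[pi, ])$coef, f$coef)
})

test_that("fit_linear flags rank deficiency instead of erroring", {
  X <- cbind(1, 1:10, 2 * (1:10))
  f <- fit_linear(rnorm(10), X)
  expect_false(f$converged)
  # too few rows
  expect_false(fit_linear(rnorm(3), cbind(1, rnorm(3), rnorm(3)))$converged)
})

test_that("all analyses collapse to the gold-standard OLS when tau = 0", {
  p <- test_params(tau = 0)
  co <- generate_cohort(p, 650, seed = 31)
  sel <- select_random(650, 260, seed = 32)
  masked <- mask_nonvalidation(co, sel)
  gold <- fit_linear(co$ir, cbind(1, co$vat, co$sex, co$age, co$tbf))

  # uncorrected: exact exposure rescaling by 1/theta
  unc <- est_uncorrected(co)
  expect_equal(unc$beta_hat, gold$coef[2] / 0.8, tolerance = 1e-10)

  std <- est_standard_rc(masked, sel)
  val <- est_validation_rc(masked, sel)
  expect_equal(std$beta_hat, gold$coef[2], tolerance = 1e-8)
  expect_equal(val$beta_hat, gold$coef[2], tolerance = 1e-8)

  # selecting the full cohort makes restricted and validation RC identical
  # to the gold-standard fit
  full <- select_random(650, 650)
  expect_equal(est_ivs_restricted(co, full)$beta_hat, gold$coef[2])
  pe <- test_params(tau = 0.44)
  coe <- generate_cohort(pe, 650, seed = 33)
  expect_equal(est_validation_rc(coe, select_random(650, 650))$beta_hat,
               fit_linear(coe$ir, cbind(1, coe$vat, coe$sex, coe$age,
                                        coe$tbf))$coef[2],
               tolerance = 1e-10)
})

test_that("estimate records carry Wald intervals around the estimate", {
  p <- test_params()
  co <- generate_cohort(p, 650, seed = 41)
  sel <- select_random(650, 260, seed = 42)
  for (rec in list(est_uncorrected(co),
                   est_ivs_restricted(co, sel),
                   est_standard_rc(co, sel),
                   est_validation_rc(co, sel))) {
    expect_true(rec$converged)
    expect_gt(rec$se, 0)
    expect_equal(rec$ci_low, rec$beta_hat - 1.96 * rec$se)
    expect_equal(rec$ci_high, rec$beta_hat + 1.96 * rec$se)
  }
})

test_that("efficient RC pools by inverse variance", {
  mk <- function(b, v, strategy = "random")
    ivsamp:::new_record("x", strategy, b, sqrt(v))
  # hand-worked: equal variances average the estimates and halve the variance
  r <- est_efficient_rc(mk(0.1, 0.04), mk(0.3, 0.04))
  expect_equal(r$beta_hat, 0.2)
  expect_equal(r$se, sqrt(0.02))
  # dominant precision
  r2 <- est_efficient_rc(mk(0.1, 1e-12), mk(0.9, 0.04))
  expect_equal(r2$beta_hat, 0.1, tolerance = 1e-6)
  # unequal weights, by hand: w = (25, 100) -> (0.2*25 + 0.4*100)/125
  r3 <- est_efficient_rc(mk(0.2, 0.04), mk(0.4, 0.01))
  expect_equal(r3$beta_hat, (0.2 * 25 + 0.4 * 100) / 125)
  expect_equal(r3$se, sqrt(1 / 125))
  # non-convergence propagates
  bad <- ivsamp:::new_record("x", "random", NA, NA, converged = FALSE)
  expect_false(est_efficient_rc(bad, mk(0.3, 0.04))$converged)
})

test_that("log-scale coefficients convert to percentage differences", {
  expect_equal(beta_to_percent(0), 0)
  expect_equal(beta_to_percent(log(1.27)), 27)
  expect_equal(beta_to_percent(0.2), 100 * (exp(0.2) - 1))
})

test_that("calibrated estimators are consistent under nondifferential error", {
  # one large-n replication per scenario cell of the factorial design
  for (lin in c(TRUE, FALSE)) {
    for (r2 in c(0.2, 0.4, 0.6, 0.8, 0.9)) {
      for (s in c(0.1, 3)) {
        lam <- lambda_from_skewness(s)
        tau <- ivsamp:::resolve_tau(scenario_config(r2, s, linear = lin))
        p <- dgm_params(tau = tau, lam = lam, linear = lin)
        co <- generate_cohort(p, 1e5,
                              seed = ivsamp:::seed_stream(round(100 * r2),
                                                          round(10 * s), lin))
        sel <- select_random(1e5, 4e4, seed = 51)
        masked <- mask_nonvalidation(co, sel)
        expect_lt(abs(est_standard_rc(masked, sel)$beta_hat - 0.2), 0.01)
        expect_lt(abs(est_validation_rc(masked, sel)$beta_hat - 0.2), 0.01)
      }
    }
  }
})

test_that("delta-method SEs match a bootstrap of the two-step procedure", {
  p <- test_params(tau = 0.44, skew = 0.1)
  co <- generate_cohort(p, 650, seed = 61)
  sel <- select_random(650, 260, seed = 62)
  masked <- mask_nonvalidation(co, sel)
  se_std <- est_standard_rc(masked, sel)$se
  se_val <- est_validation_rc(masked, sel)$se
  set.seed(63)
  B <- 500
  boots <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(650, replace = TRUE)
    bco <- masked[idx, ]
    bsel <- ivsamp:::new_selection("random", which(bco$in_validation),
                                   sum(bco$in_validation))
    boots[b, 1] <- est_standard_rc(bco, bsel)$beta_hat
    boots[b, 2] <- est_validation_rc(bco, bsel)$beta_hat
  }
  expect_gt(se_std / sd(boots[, 1]), 0.9)
  expect_lt(se_std / sd(boots[, 1]), 1.1)
  expect_gt(se_val / sd(boots[, 2]), 0.9)
  expect_lt(se_val / sd(boots[, 2]), 1.1)
})
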