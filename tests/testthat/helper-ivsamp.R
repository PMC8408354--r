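# Shared fixtures and small oracles for the test suite.

# Moment-based sample skewness.
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Analytic marginal variance of the gold standard under the generator:
# VAT = -1.4 - 1.1 sex + 0.019 age + 0.9 e_T + eps after substituting the
# TBF equation, with Var(sex) = 1/4, Var(age) = 400/12, Var(e_T) = 0.5,
# Var(eps) = 0.5 and all components independent.
VAT_VARIANCE <- 1.1^2 / 4 + 0.019^2 * 400 / 12 + 0.81 * 0.5 + 0.5

# Default nondifferential parameter set used across tests.
test_params <- function(tau = 0.44, skew = 1, ...) {
  dgm_params(tau = tau, lam = lambda_from_skewness(skew), ...)
}

# The full factorial of the study's nondifferential conditions.
grid_configs <- function(val_fraction, n_reps, seed) {
  g <- expand.grid(r2 = c(0.2, 0.4, 0.6, 0.8, 0.9),
                   skew = c(0.1, 1, 1.5, 3),
                   lin = c(TRUE, FALSE))
  lapply(seq_len(nrow(g)), function(i)
    scenario_config(g$r2[i], g$skew[i], linear = g$lin[i],
                    val_fraction = val_fraction, n_reps = n_reps,
                    seed = seed))
}

# Grid results are expensive; compute each fraction's grid once per test
# run and share it across test files.
.grid_cache <- new.env(parent = emptyenv())
cached_grid <- function(val_fraction, n_reps = 500L, seed = 11L) {
  key <- paste(val_fraction, n_reps, seed)
  if (is.null(.grid_cache[[key]]))
    .grid_cache[[key]] <- run_grid(grid_configs(val_fraction, n_reps, seed))
  .grid_cache[[key]]
}

cached_differential <- function(n_reps = 2000L, seed = 17L) {
  key <- paste("diff", n_reps, seed)
  if (is.null(.grid_cache[[key]])) {
    cfg <- scenario_config(r2_target = 0.8, skewness = 0.1,
                           differential = TRUE, tau = 0.44,
                           val_fraction = 0.4, n_reps = n_reps, seed = seed)
    .grid_cache[[key]] <- run_scenario(cfg)
  }
  .grid_cache[[key]]
}
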