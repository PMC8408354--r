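# Monte Carlo engine: replications over a factorial scenario grid, the
# performance measures (bias, MSE, coverage, empirical and model-based SE)
# with Monte Carlo standard errors, and MSE-efficiency comparisons between
# sampling strategies.

STRATEGIES <- c("random", "stratified", "extremes")
RC_METHODS <- c("ivs_restricted", "standard_rc", "validation_rc", "efficient_rc")

#' Define one simulation scenario
#'
#' One cell of the factorial design: target explained variance of the
#' substitute given the gold standard (`r2_target`), target skewness of
#' the gold-standard residual, linear vs nonlinear error model,
#' differential-error flag, validation fraction, cohort size, number of
#' replications and master seed.
#'
#' The measurement-error scale `tau` is normally calibrated from
#' `r2_target` via [tau_from_r2()]; a fixed value can be supplied instead
#' (the differential scenario uses the fixed `tau = 0.44`, which
#' corresponds to R-squared 0.8 under the linear model).
#'
#' @param r2_target Explained variance of WC given VAT, in (0, 1).
#' @param skewness Target skewness of the VAT residual, positive.
#' @param linear Logical; linear vs square-root error model.
#' @param differential Logical; differential-error variant.
#' @param val_fraction Validation fraction in (0, 1].
#' @param n Cohort size (default 650).
#' @param n_reps Monte Carlo replications (default 5000).
#' @param seed Master seed.
#' @param beta True exposure coefficient (the estimand), default 0.2.
#' @param theta Calibration slope, default 0.8.
#' @param tau Optional fixed measurement-error SD overriding calibration.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(r2_target, skewness, linear = TRUE,
                            differential = FALSE, val_fraction = 0.4,
                            n = 650L, n_reps = 5000L, seed = 1L,
                            beta = 0.2, theta = 0.8, tau = NULL) {
  if (!is.numeric(r2_target) || r2_target <= 0 || r2_target >= 1)
    stop("`r2_target` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(skewness) || skewness <= 0)
    stop("`skewness` must be positive", call. = FALSE)
  if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction > 1)
    stop("`val_fraction` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("`n` must be positive", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be positive", call. = FALSE)
  structure(
    list(r2_target = r2_target, skewness = skewness, linear = isTRUE(linear),
         differential = isTRUE(differential), val_fraction = val_fraction,
         n = as.integer(n), n_reps = as.integer(n_reps),
         seed = as.integer(seed), beta = beta, theta = theta, tau = tau),
    class = "scenario_config")
}

# tau cache: tau is a deterministic property of (r2, lambda, theta), so
# solve once per distinct combination per session. The calibration always
# uses the LINEAR error model: the explained-variance targets index the
# scale of the measurement error, and the nonlinear variant swaps the mean
# function while keeping the same tau (the nonlinear relation caps the
# linear R^2 of WC on VAT below 0.9, so the high targets have no exact
# nonlinear solution and are not meant to).
tau_cache <- new.env(parent = emptyenv())

resolve_tau <- function(config) {
  if (!is.null(config$tau)) return(config$tau)
  lam <- lambda_from_skewness(config$skewness)
  key <- paste(config$r2_target, signif(lam, 10), config$theta, sep = "|")
  if (!is.null(tau_cache[[key]])) return(tau_cache[[key]])
  p <- dgm_params(beta = config$beta, theta = config$theta, tau = 0,
                  lam = lam, linear = TRUE)
  tau <- tau_from_r2(config$r2_target, p)
  tau_cache[[key]] <- tau
  tau
}

scenario_params <- function(config, tau) {
  dgm_params(beta = config$beta, theta = config$theta, tau = tau,
             lam = lambda_from_skewness(config$skewness),
             linear = config$linear, differential = config$differential)
}

#' Run a single replication of a scenario
#'
#' Generates one cohort from the replication's own substream of the master
#' seed, then computes all analyses: the uncorrected analysis once, and
#' for each sampling strategy (random, stratified, extremes) the
#' IVS-restricted, standard, validation and efficient regression
#' calibration analyses — 13 estimate records in total. Identical
#' `(seed, rep_index)` pairs give bit-identical records, so any single
#' replication can be regenerated in isolation.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replication number (1-based).
#' @param tau Optional pre-resolved measurement-error SD; resolved from
#'   `config` when `NULL`.
#' @return A list of 13 `estimate_record`s.
#' @export
run_replication <- function(config, rep_index, tau = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(tau)) tau <- resolve_tau(config)
  params <- scenario_params(config, tau)
  rep_seed <- seed_stream(config$seed, scenario_key(config), rep_index)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rep_seed)
  cohort <- generate_cohort(params, config$n)
  m <- validation_size(config$n, config$val_fraction)
  records <- vector("list", 1L + 4L * length(STRATEGIES))
  records[[1L]] <- est_uncorrected(cohort)
  i <- 2L
  for (strategy in STRATEGIES) {
    sel <- select_validation(strategy, cohort$wc, m)
    masked <- mask_nonvalidation(cohort, sel)
    r_ivs <- est_ivs_restricted(masked, sel)
    r_std <- est_standard_rc(masked, sel)
    r_val <- est_validation_rc(masked, sel)
    r_eff <- est_efficient_rc(r_ivs, r_std)
    records[[i]] <- r_ivs; records[[i + 1L]] <- r_std
    records[[i + 2L]] <- r_val; records[[i + 3L]] <- r_eff
    i <- i + 4L
  }
  records
}

#' Summarize replications into performance measures
#'
#' Computes, over converged replications: bias `mean(b) - beta`,
#' percentage bias `100 * bias / beta`, MSE `mean((b - beta)^2)`, coverage
#' of the 95% Wald intervals, empirical SE (sample SD of the estimates)
#' and model SE (square root of the mean model-based variance), each of
#' bias, MSE and coverage with its Monte Carlo standard error:
#' `mcse_bias = emp_se / sqrt(K)`,
#' `mcse_mse = sqrt(sum(((b - beta)^2 - mse)^2) / (K (K - 1)))`,
#' `mcse_coverage = sqrt(coverage (1 - coverage) / K)`.
#'
#' @param beta_hat Vector of point estimates.
#' @param se Vector of model-based standard errors.
#' @param truth True coefficient value.
#' @param converged Logical vector; non-converged replications are dropped
#'   (and counted via `n_reps_used`).
#' @return A one-row `data.frame` (a performance summary).
#' @export
summarize_performance <- function(beta_hat, se, truth, converged = NULL) {
  if (is.null(converged)) converged <- is.finite(beta_hat) & is.finite(se)
  b <- beta_hat[converged]; s <- se[converged]
  K <- length(b)
  if (K < 2L) stop("need at least 2 converged replications", call. = FALSE)
  covered <- (b - Z95 * s <= truth) & (truth <= b + Z95 * s)
  bias <- mean(b) - truth
  sq <- (b - truth)^2
  mse <- mean(sq)
  coverage <- mean(covered)
  emp_se <- stats::sd(b)
  data.frame(
    n_reps_used = K,
    bias = bias,
    pct_bias = 100 * bias / truth,
    mse = mse,
    coverage = coverage,
    emp_se = emp_se,
    model_se = sqrt(mean(s^2)),
    mcse_bias = emp_se / sqrt(K),
    mcse_mse = sqrt(sum((sq - mse)^2) / (K * (K - 1))),
    mcse_coverage = sqrt(coverage * (1 - coverage) / K))
}

#' Run all replications of one scenario
#'
#' @param config A [scenario_config()].
#' @param tau Optional pre-resolved measurement-error SD.
#' @return A `data.frame` with one row per (strategy, method) — 13 rows —
#'   carrying the scenario descriptors and all performance measures.
#' @export
run_scenario <- function(config, tau = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(tau)) tau <- resolve_tau(config)
  K <- config$n_reps
  nrec <- 1L + 4L * length(STRATEGIES)
  betas <- matrix(NA_real_, K, nrec)
  ses <- matrix(NA_real_, K, nrec)
  for (r in seq_len(K)) {
    recs <- run_replication(config, r, tau = tau)
    betas[r, ] <- vapply(recs, `[[`, numeric(1), "beta_hat")
    ses[r, ] <- vapply(recs, `[[`, numeric(1), "se")
  }
  labels <- run_replication(config, 1L, tau = tau)
  out <- do.call(rbind, lapply(seq_len(nrec), function(j) {
    cbind(data.frame(method = labels[[j]]$method,
                     strategy = labels[[j]]$strategy),
          summarize_performance(betas[, j], ses[, j], config$beta))
  }))
  cbind(data.frame(r2_target = config$r2_target, skewness = config$skewness,
                   linear = config$linear, differential = config$differential,
                   val_fraction = config$val_fraction, n = config$n,
                   n_reps = K, tau = tau), out)
}

#' Run a grid of scenarios
#'
#' Runs every scenario in `configs` and stacks the performance summaries.
#' Results are deterministic given each scenario's master seed and are
#' independent of execution order and of `workers`, because every
#' replication draws from its own seed substream. A failing scenario is
#' isolated: its error message is collected in the `"failures"` attribute
#' and the remaining scenarios still run.
#'
#' @param configs A list of [scenario_config()] objects.
#' @param workers Number of parallel workers ([parallel::mclapply()]);
#'   default 1.
#' @param progress Logical; print one line per completed scenario.
#' @return A long-format `data.frame`, one row per
#'   (scenario, strategy, method).
#' @export
run_grid <- function(configs, workers = 1L, progress = FALSE) {
  if (length(configs) == 0L) stop("empty scenario grid", call. = FALSE)
  stopifnot(all(vapply(configs, inherits, logical(1), "scenario_config")))
  # Resolve every tau up front (sequentially) so forked workers share the
  # cache and tau stays a pure function of the scenario.
  taus <- vapply(configs, resolve_tau, numeric(1))
  one <- function(i) {
    res <- tryCatch(run_scenario(configs[[i]], tau = taus[[i]]),
                    error = function(e) e)
    if (progress && !inherits(res, "error"))
      message(sprintf("scenario %d/%d done (r2=%.2g skew=%.2g linear=%s frac=%.2g)",
                      i, length(configs), configs[[i]]$r2_target,
                      configs[[i]]$skewness, configs[[i]]$linear,
                      configs[[i]]$val_fraction))
    res
  }
  results <- if (workers > 1L)
    parallel::mclapply(seq_along(configs), one, mc.cores = workers)
  else lapply(seq_along(configs), one)
  errs <- vapply(results, inherits, logical(1), "error")
  out <- do.call(rbind, c(results[!errs], list(make.row.names = FALSE)))
  if (any(errs)) {
    msgs <- vapply(results[errs], conditionMessage, character(1))
    warning(sprintf("%d scenario(s) failed: %s", sum(errs),
                    paste(msgs, collapse = "; ")), call. = FALSE)
    attr(out, "failures") <- data.frame(scenario = which(errs), message = msgs)
  }
  out
}

#' Average MSE decrease of a sampling strategy relative to a baseline
#'
#' For each scenario in the table, computes the percentage decrease in MSE
#' `100 * (1 - MSE_strategy / MSE_baseline)` for the given analysis
#' method, then returns the unweighted arithmetic mean over scenarios
#' (also returning the per-scenario values).
#'
#' @param table Output of [run_grid()] (or [run_scenario()]).
#' @param strategy Sampling strategy to evaluate.
#' @param method Analysis method (e.g. `"validation_rc"`).
#' @param baseline Baseline strategy (default `"random"`).
#' @return A list with `average` (percent) and `per_scenario`
#'   (`data.frame` of scenario descriptors plus `pct_decrease`).
#' @export
mse_reduction <- function(table, strategy, method, baseline = "random") {
  keys <- c("r2_target", "skewness", "linear", "differential", "val_fraction")
  a <- table[table$strategy == strategy & table$method == method, ]
  b <- table[table$strategy == baseline & table$method == method, ]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop(sprintf("no rows for method '%s' with strategy '%s' and baseline '%s'",
                 method, strategy, baseline), call. = FALSE)
  merged <- merge(a[, c(keys, "mse")], b[, c(keys, "mse")],
                  by = keys, suffixes = c("_strategy", "_baseline"))
  missing_a <- nrow(a) - nrow(merged)
  if (missing_a != 0L || nrow(b) != nrow(merged))
    stop(sprintf(
      "baseline '%s' rows missing for %d scenario(s) of strategy '%s'",
      baseline, abs(nrow(a) - nrow(merged)), strategy), call. = FALSE)
  merged$pct_decrease <- 100 * (1 - merged$mse_strategy / merged$mse_baseline)
  list(average = mean(merged$pct_decrease), per_scenario = merged)
}

#' Export results in nested-loop order
#'
#' Orders the results table for nested-loop-style displays: linearity as
#' the outer loop, then skewness, then the explained variance R-squared as
#' the innermost loop, and adds a `scenario_order` column.
#'
#' @param table Output of [run_grid()].
#' @return The reordered table with a `scenario_order` column.
#' @export
nested_loop_export <- function(table) {
  ord <- order(!table$linear, table$skewness, table$r2_target,
               table$strategy, table$method)
  out <- table[ord, ]
  key <- paste(out$linear, out$skewness, out$r2_target)
  out$scenario_order <- match(key, unique(key))
  rownames(out) <- NULL
  out
}
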