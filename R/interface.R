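# Configuration files, reproduction entry points and run manifests.
#
# A config is a YAML file with either grid keys (vectors are crossed into
# the full factorial) or an explicit `scenarios:` list. Grid keys:
#   r2           explained variance targets, each in (0, 1)
#   skewness     residual-skewness targets, each > 0
#   linear       logical (one or both of true/false)
#   differential logical
#   val_fraction validation fraction(s) in (0, 1]
#   n            cohort size; n_reps replications; seed master seed
#   beta, theta  estimand and calibration slope (optional)
#   tau          fixed measurement-error SD overriding R^2 calibration
#                (optional; used by the differential scenario)

CONFIG_KEYS <- c("r2", "skewness", "linear", "differential", "val_fraction",
                 "n", "n_reps", "seed", "beta", "theta", "tau")

# YAML 1.1 treats a bare `n` as a boolean, so the cohort-size key comes back
# named "FALSE"; restore it.
normalize_keys <- function(x) {
  if (length(x) == 0L) return(x)
  names(x)[names(x) == "FALSE"] <- "n"
  # mixed int/double sequences come back as lists; flatten numeric keys
  numkeys <- setdiff(CONFIG_KEYS, c("linear", "differential"))
  for (k in intersect(names(x), numkeys))
    if (is.list(x[[k]])) x[[k]] <- as.numeric(unlist(x[[k]]))
  x
}

#' Load a scenario grid from a YAML config
#'
#' Expands grid-form keys into the full cross-product of scenarios, or
#' reads an explicit `scenarios:` list, validating every value against the
#' scenario invariants. Unknown keys and out-of-range values raise an
#' error naming the offending field.
#'
#' @param path Path to a YAML config file.
#' @return A list of [scenario_config()] objects.
#' @examples
#' cfg <- system.file("configs", "differential.yaml", package = "ivsamp")
#' length(load_config(cfg))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- normalize_keys(yaml::read_yaml(path))
  if (length(raw) == 0L) stop("config file is empty: ", path, call. = FALSE)
  if (!is.null(raw$scenarios)) {
    extra <- setdiff(names(raw), "scenarios")
    if (length(extra))
      stop("unknown config key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    return(lapply(raw$scenarios, scenario_from_list))
  }
  extra <- setdiff(names(raw), CONFIG_KEYS)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  need <- c("r2", "skewness")
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(
    r2 = raw$r2, skewness = raw$skewness,
    linear = if (is.null(raw$linear)) TRUE else raw$linear,
    differential = if (is.null(raw$differential)) FALSE else raw$differential,
    val_fraction = if (is.null(raw$val_fraction)) 0.4 else raw$val_fraction,
    KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("config expands to an empty grid", call. = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_config(
      r2_target = grid$r2[i], skewness = grid$skewness[i],
      linear = grid$linear[i], differential = grid$differential[i],
      val_fraction = grid$val_fraction[i],
      n = raw$n %||% 650L, n_reps = raw$n_reps %||% 5000L,
      seed = raw$seed %||% 1L, beta = raw$beta %||% 0.2,
      theta = raw$theta %||% 0.8, tau = raw$tau))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_from_list <- function(x) {
  x <- normalize_keys(x)
  extra <- setdiff(names(x), c("r2", CONFIG_KEYS[-1]))
  if (length(extra))
    stop("unknown scenario key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  scenario_config(
    r2_target = x$r2, skewness = x$skewness,
    linear = x$linear %||% TRUE, differential = x$differential %||% FALSE,
    val_fraction = x$val_fraction %||% 0.4, n = x$n %||% 650L,
    n_reps = x$n_reps %||% 5000L, seed = x$seed %||% 1L,
    beta = x$beta %||% 0.2, theta = x$theta %||% 0.8, tau = x$tau)
}

#' Write a scenario grid to a YAML config
#'
#' Writes the explicit `scenarios:` list form, so that
#' `load_config(write_config(grid, path))` reproduces the identical grid.
#'
#' @param configs List of [scenario_config()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(configs, path) {
  stopifnot(all(vapply(configs, inherits, logical(1), "scenario_config")))
  scen <- lapply(configs, function(cc) {
    out <- list(r2 = cc$r2_target, skewness = cc$skewness, linear = cc$linear,
                differential = cc$differential,
                val_fraction = cc$val_fraction, n = cc$n, n_reps = cc$n_reps,
                seed = cc$seed, beta = cc$beta, theta = cc$theta)
    if (!is.null(cc$tau)) out$tau <- cc$tau
    out
  })
  yaml::write_yaml(list(scenarios = scen), path, precision = 15L)
  invisible(path)
}

config_digest <- function(configs) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(configs, tmp)
  unname(tools::md5sum(tmp))
}

#' Build a run manifest
#'
#' Captures what identifies a run: a content digest of the scenario grid,
#' the master seed(s), the package version, a timestamp and the output
#' paths. Identical digest, seeds and version imply bit-identical result
#' tables.
#'
#' @param configs List of [scenario_config()] objects.
#' @param outputs Character vector of output paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(configs, outputs = character()) {
  structure(list(
    config_digest = config_digest(configs),
    master_seed = unique(vapply(configs, `[[`, integer(1), "seed")),
    package_version = as.character(utils::packageVersion("ivsamp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs), class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
    flags[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

log_convergence <- function(table) {
  keys <- c("r2_target", "skewness", "linear", "val_fraction")
  frac <- stats::aggregate(table$n_reps_used / table$n_reps,
                           by = table[keys], FUN = min)
  bad <- frac[frac$x < 1, , drop = FALSE]
  if (nrow(bad) > 0L)
    for (i in seq_len(nrow(bad)))
      message(sprintf(
        "warning: scenario r2=%.2g skew=%.2g linear=%s frac=%.2g: %.1f%% of fits failed",
        bad$r2_target[i], bad$skewness[i], bad$linear[i], bad$val_fraction[i],
        100 * (1 - bad$x[i])))
  else message("all fits converged in every scenario")
}

reduction_table <- function(table) {
  combos <- expand.grid(strategy = c("stratified", "extremes"),
                        method = RC_METHODS, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    red <- mse_reduction(table, combos$strategy[i], combos$method[i])
    data.frame(strategy = combos$strategy[i], method = combos$method[i],
               avg_pct_decrease = red$average,
               n_scenarios = nrow(red$per_scenario))
  }))
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{Run a config (`--config PATH`), writing
#'     `results.csv` and `manifest.json` to `--out-dir`. Optional
#'     overrides: `--seed`, `--reps`, `--workers`, and `--subset i:j` to
#'     run a contiguous scenario range.}
#'   \item{`reduce`}{Read a results CSV (`--results PATH`) and write
#'     `reductions.csv` (average MSE decrease of stratified and extremes
#'     sampling vs random, per analysis method).}
#'   \item{`demo`}{Run one small scenario end to end (200 replications)
#'     and print its 13-row performance summary.}
#' }
#' A thin `Rscript` wrapper is installed at
#' `system.file("cli", "ivsamp.R", package = "ivsamp")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on failure.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: ivsamp <simulate|reduce|demo> [--flags]", call. = FALSE)
    cmd <- args[[1L]]
    flags <- parse_cli_flags(args[-1L])
    out_dir <- flags$out_dir %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    switch(cmd,
      simulate = {
        if (is.null(flags$config)) stop("simulate needs --config", call. = FALSE)
        configs <- load_config(flags$config)
        if (!is.null(flags$subset)) {
          rng <- as.integer(strsplit(flags$subset, ":")[[1L]])
          configs <- configs[seq.int(rng[1L], rng[2L])]
        }
        for (i in seq_along(configs)) {
          if (!is.null(flags$seed)) configs[[i]]$seed <- as.integer(flags$seed)
          if (!is.null(flags$reps)) configs[[i]]$n_reps <- as.integer(flags$reps)
        }
        res <- run_grid(configs, workers = as.integer(flags$workers %||% 1L),
                        progress = TRUE)
        log_convergence(res)
        res_path <- file.path(out_dir, "results.csv")
        utils::write.csv(res, res_path, row.names = FALSE)
        write_manifest(run_manifest(configs, outputs = res_path),
                       file.path(out_dir, "manifest.json"))
        message("wrote ", res_path)
      },
      reduce = {
        if (is.null(flags$results)) stop("reduce needs --results", call. = FALSE)
        res <- utils::read.csv(flags$results)
        red <- reduction_table(res)
        red_path <- file.path(out_dir, "reductions.csv")
        utils::write.csv(red, red_path, row.names = FALSE)
        print(red)
        message("wrote ", red_path)
      },
      demo = {
        cfg <- scenario_config(r2_target = 0.6, skewness = 1.5,
                               n_reps = as.integer(flags$reps %||% 200L),
                               seed = as.integer(flags$seed %||% 1L))
        res <- run_scenario(cfg)
        print(res[, c("method", "strategy", "pct_bias", "mse", "coverage",
                      "emp_se", "model_se")], digits = 3)
        res_path <- file.path(out_dir, "results.csv")
        utils::write.csv(res, res_path, row.names = FALSE)
        message("wrote ", res_path)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
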