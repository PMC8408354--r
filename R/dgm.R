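# Data-generating mechanism: synthetic cohorts with a gold-standard exposure
# (VAT), an error-prone substitute (WC), confounders (sex, age, total body
# fat) and a continuous outcome (insulin resistance, log scale).

#' Parameters of the data-generating mechanism
#'
#' Bundles the parameters of the synthetic cohort generator. The cohort
#' model is, in generative order:
#' \itemize{
#'   \item sex ~ Bernoulli(0.5); age ~ Uniform(45, 65) years;
#'   \item TBF | sex, age ~ Normal(-2 + sex + 0.01 age, variance 0.5);
#'   \item VAT = 0.4 - 2 sex + 0.01 age + 0.9 TBF + eps, where eps is a
#'     mean-centred Gamma(shape 6 lambda, scale sqrt(0.5/(6 lambda)))
#'     residual with variance exactly 0.5 and skewness 2/sqrt(6 lambda)
#'     for every lambda;
#'   \item WC | VAT ~ Normal(theta VAT, tau^2) (linear error model),
#'     Normal(theta t(VAT), tau^2) with the sign-preserving square root
#'     t(v) = sign(v) sqrt(|v|) (nonlinear), or
#'     Normal(theta VAT + tau U, tau^2) with U ~ Bernoulli(0.5)
#'     (differential);
#'   \item IR | VAT, sex, age, TBF ~ Normal(0.5 + beta VAT - 0.5 sex +
#'     0.01 age + 0.3 TBF (+ sqrt(0.3) U when differential), variance 0.3).
#' }
#' All second parameters of normal distributions are variances. The latent
#' binary variable U ties the substitute's error to the outcome in the
#' differential variant and is constant zero otherwise.
#'
#' @param beta Coefficient of VAT in the outcome model (the estimand).
#' @param theta Calibration slope of WC on (transformed) VAT.
#' @param tau Residual standard deviation of WC given VAT; `tau >= 0`.
#' @param lam Gamma shape control; the VAT residual has shape `6 * lam`.
#'   Must be positive. See [lambda_from_skewness()].
#' @param linear Logical; `FALSE` selects the nonlinear (square-root)
#'   error model for WC.
#' @param differential Logical; `TRUE` selects the differential error
#'   variant in which WC and IR share the latent variable U.
#'
#' @return An object of class `dgm_params` (a named list).
#' @examples
#' dgm_params(tau = 0.44, lam = lambda_from_skewness(0.1))
#' @export
dgm_params <- function(beta = 0.2, theta = 0.8, tau, lam,
                       linear = TRUE, differential = FALSE) {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0)
    stop("`lam` must be a single positive number", call. = FALSE)
  structure(
    list(beta = beta, theta = theta, tau = tau, lam = lam,
         linear = isTRUE(linear), differential = isTRUE(differential)),
    class = "dgm_params"
  )
}

#' Gamma shape control from a target residual skewness
#'
#' The gold-standard residual eps has a gamma distribution with shape
#' `6 * lambda`, whose skewness is `2 / sqrt(6 * lambda)`. Inverting gives
#' the unique `lambda = 2 / (3 * s^2)` attaining a target skewness `s`,
#' while the scale `sqrt(0.5 / (6 * lambda))` keeps the residual variance
#' fixed at 0.5 for every `lambda`.
#'
#' @param s Target skewness of the VAT residual; must be positive.
#' @return The shape control `lambda`.
#' @examples
#' lambda_from_skewness(1)    # 2/3
#' lambda_from_skewness(0.1)  # ~66.67, nearly symmetric residuals
#' @export
lambda_from_skewness <- function(s) {
  if (!is.numeric(s) || any(is.na(s)) || any(s <= 0))
    stop("target skewness `s` must be positive", call. = FALSE)
  2 / (3 * s^2)
}

#' Sign-preserving square root
#'
#' Transform used by the nonlinear measurement-error model. VAT can be
#' negative on the standardized scale of the generator, so the square root
#' is extended as `sign(v) * sqrt(|v|)`, which is continuous, strictly
#' increasing and odd.
#'
#' @param v Numeric vector.
#' @return `sign(v) * sqrt(abs(v))`.
#' @export
signed_sqrt <- function(v) sign(v) * sqrt(abs(v))

# Latent cohort pieces shared by generate_cohort() and the tau calibration:
# confounders, gold standard, and the standardized WC noise (so WC at any
# tau is exposure_mean + tau * z without redrawing).
generate_latent <- function(params, n) {
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 45, 65)
  tbf <- stats::rnorm(n, -2 + sex + 0.01 * age, sqrt(0.5))
  shape <- 6 * params$lam
  scale <- sqrt(0.5 / shape)
  eps <- stats::rgamma(n, shape = shape, scale = scale) - shape * scale
  vat <- 0.4 - 2 * sex + 0.01 * age + 0.9 * tbf + eps
  u <- if (params$differential) stats::rbinom(n, 1L, 0.5) else integer(n)
  z <- stats::rnorm(n)
  list(sex = sex, age = age, tbf = tbf, eps = eps, vat = vat, u = u, z = z)
}

wc_mean <- function(params, vat, u) {
  g <- if (params$linear) vat else signed_sqrt(vat)
  m <- params$theta * g
  if (params$differential) m <- m + params$tau * u
  m
}

#' Generate a synthetic cohort
#'
#' Draws one cohort of size `n` from the mechanism described in
#' [dgm_params()]. The gold standard `vat` is observed for every row at
#' generation time; restricting it to a validation sample is a separate,
#' explicit step ([mask_nonvalidation()]).
#'
#' @param params A [dgm_params()] object.
#' @param n Cohort size; at least 1.
#' @param seed Optional integer seed; when supplied the generator is
#'   reproducible and does not disturb the caller's RNG stream.
#' @return A `data.frame` with columns `sex`, `age`, `tbf`, `vat`, `wc`,
#'   `ir`, `u` and `in_validation` (initially all `NA`).
#' @examples
#' p <- dgm_params(tau = 0.44, lam = lambda_from_skewness(1))
#' head(generate_cohort(p, n = 650, seed = 1))
#' @export
generate_cohort <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "dgm_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive cohort size", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lat <- generate_latent(params, n)
  wc <- wc_mean(params, lat$vat, lat$u) + params$tau * lat$z
  ir_mean <- 0.5 + params$beta * lat$vat - 0.5 * lat$sex +
    0.01 * lat$age + 0.3 * lat$tbf
  if (params$differential) ir_mean <- ir_mean + sqrt(0.3) * lat$u
  ir <- stats::rnorm(n, ir_mean, sqrt(0.3))
  data.frame(sex = lat$sex, age = lat$age, tbf = lat$tbf, vat = lat$vat,
             wc = wc, ir = ir, u = lat$u, in_validation = rep(NA, n))
}

#' Calibrate the measurement-error scale to a target R-squared
#'
#' Solves for the residual standard deviation `tau` of WC given VAT such
#' that the coefficient of determination of the simple linear regression
#' of WC on VAT, in a single large simulated cohort of size `n_cal`,
#' equals `r2` to within `1e-3`. The cohort's latent draws (VAT and the
#' standardized WC noise) are generated once and held fixed, so the
#' realized R-squared is a smooth, strictly decreasing function of `tau`
#' and the root is found by monotone bisection ([stats::uniroot()]).
#'
#' For the linear error model, `tau` admits the closed form
#' `tau^2 = theta^2 Var(VAT) (1 - R^2) / R^2`; the empirical solver agrees
#' with it up to Monte Carlo error in `Var(VAT)` and also covers the
#' nonlinear model, where no closed form is available.
#'
#' `tau` is treated as a property of the scenario, not of a particular
#' simulation run: by default the calibration cohort uses a fixed seed
#' derived from the scenario parameters, so repeated calls return the
#' identical value.
#'
#' @param r2 Target explained variance of WC given VAT, in (0, 1).
#' @param params A [dgm_params()] object; its `tau` is ignored.
#' @param n_cal Calibration cohort size (default one million).
#' @param seed Seed for the calibration cohort; defaults to a fixed value
#'   derived from `r2`, `lam` and the linearity flag.
#' @return The calibrated `tau`.
#' @examples
#' \donttest{
#' p <- dgm_params(tau = 0, lam = lambda_from_skewness(0.1))
#' tau_from_r2(0.8, p)  # ~0.44
#' }
#' @export
tau_from_r2 <- function(r2, params, n_cal = 1e6, seed = NULL) {
  stopifnot(inherits(params, "dgm_params"))
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 <= 0 || r2 >= 1)
    stop("`r2` must lie strictly between 0 and 1", call. = FALSE)
  if (is.null(seed))
    seed <- seed_stream(round(1000 * r2), round(1000 * params$lam),
                        as.integer(params$linear))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lat <- generate_latent(params, as.integer(n_cal))
  m <- wc_mean(params, lat$vat, lat$u)
  # Realized R^2 of WC = m + tau*z on VAT, from fixed cross-moments:
  # R^2(tau) = cov(m + tau z, vat)^2 / (var(m + tau z) var(vat)).
  v_vat <- stats::var(lat$vat)
  v_m <- stats::var(m); v_z <- stats::var(lat$z)
  c_mv <- stats::cov(m, lat$vat); c_zv <- stats::cov(lat$z, lat$vat)
  c_mz <- stats::cov(m, lat$z)
  r2_at <- function(tau)
    (c_mv + tau * c_zv)^2 /
      ((v_m + 2 * tau * c_mz + tau^2 * v_z) * v_vat)
  f <- function(tau) r2_at(tau) - r2
  hi <- 1
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(0) < 0 || f(hi) > 0)
    stop(sprintf(
      "cannot reach R^2 = %.3f: achievable range is (%.4f, %.4f]",
      r2, r2_at(hi), r2_at(0)), call. = FALSE)
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}
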