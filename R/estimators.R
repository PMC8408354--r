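# The five analyses applied to each cohort: uncorrected, restricted to the
# internal validation sample (IVS), and standard / validation / efficient
# regression calibration. Each returns the exposure coefficient with a
# standard error and Wald 95% interval.

Z95 <- 1.96

new_record <- function(method, strategy, beta_hat, se, converged = TRUE) {
  if (!converged || !is.finite(beta_hat) || !is.finite(se) || se <= 0) {
    beta_hat <- NA_real_; se <- NA_real_; converged <- FALSE
  }
  structure(
    list(method = method, strategy = strategy, beta_hat = beta_hat, se = se,
         ci_low = beta_hat - Z95 * se, ci_high = beta_hat + Z95 * se,
         converged = converged),
    class = "estimate_record")
}

#' @export
as.data.frame.estimate_record <- function(x, ...) {
  data.frame(method = x$method, strategy = x$strategy, beta_hat = x$beta_hat,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             converged = x$converged)
}

#' Ordinary least squares with model-based covariance
#'
#' Minimal OLS workhorse: coefficients and the model-based covariance
#' `sigma^2 (X'X)^{-1}` with the unbiased residual-variance estimator.
#' Rank deficiency (or too few rows) is reported through `converged`
#' rather than an error, so a failed replication can be recorded and
#' dropped by the simulation engine.
#'
#' @param y Outcome vector.
#' @param X Design matrix including the intercept column.
#' @return A list with `coef`, `cov`, `sigma2`, `converged`.
#' @export
fit_linear <- function(y, X) {
  n <- nrow(X); p <- ncol(X)
  fail <- list(coef = rep(NA_real_, p), cov = matrix(NA_real_, p, p),
               sigma2 = NA_real_, converged = FALSE)
  if (n < p + 1L) return(fail)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(fail)
  XtXinv <- chol2inv(ch)
  coef <- drop(XtXinv %*% crossprod(X, y))
  res <- y - drop(X %*% coef)
  sigma2 <- sum(res^2) / (n - p)
  list(coef = coef, cov = sigma2 * XtXinv, sigma2 = sigma2, converged = TRUE)
}

design_matrix <- function(exposure, cohort) {
  cbind(1, exposure, cohort$sex, cohort$age, cohort$tbf)
}

#' Uncorrected analysis
#'
#' Regresses the outcome on the error-prone substitute plus confounders
#' over the full cohort, ignoring measurement error. Under classical
#' nondifferential error this estimate is attenuated toward zero (and
#' rescaled by the calibration slope).
#'
#' @param cohort A cohort data frame.
#' @return An `estimate_record` (strategy `"none"`).
#' @export
est_uncorrected <- function(cohort) {
  f <- fit_linear(cohort$ir, design_matrix(cohort$wc, cohort))
  new_record("uncorrected", "none", f$coef[2], sqrt(f$cov[2, 2]),
             f$converged)
}

#' Analysis restricted to the internal validation sample
#'
#' Regresses the outcome on the gold standard plus confounders using only
#' the validation rows. Unbiased under nondifferential error and random
#' sampling; selection on the error-prone measure combined with
#' differential error opens a collider path and biases it.
#'
#' @param cohort A cohort data frame (gold standard observed in `sel`).
#' @param sel A `validation_selection`.
#' @return An `estimate_record`.
#' @export
est_ivs_restricted <- function(cohort, sel) {
  stopifnot(inherits(sel, "validation_selection"))
  sub <- cohort[sel$indices, ]
  f <- fit_linear(sub$ir, design_matrix(sub$vat, sub))
  new_record("ivs_restricted", sel$strategy, f$coef[2], sqrt(f$cov[2, 2]),
             f$converged)
}

# Stacked estimating-equation (sandwich) variance for the two-step
# regression-calibration estimators. Parameters eta = (alpha, gamma):
# alpha from the calibration model VAT ~ WC + Z on the validation rows,
# gamma from the outcome model IR ~ exposure(alpha) + Z on all rows, where
# exposure is the calibration prediction (standard RC) or the observed
# gold standard inside the validation sample and the prediction outside it
# (validation RC). The bread picks up the dependence of the outcome-stage
# design on alpha (the multivariate delta method); the meat is the
# empirical outer product of the stacked scores.
rc_sandwich_se <- function(X1, res1, inval, X2, res2, gamma_exp, dep_rows) {
  p <- ncol(X1)
  A11 <- crossprod(X1[inval, , drop = FALSE])
  A22 <- crossprod(X2)
  Xd <- X1[dep_rows, , drop = FALSE]
  A21 <- gamma_exp * crossprod(X2[dep_rows, , drop = FALSE], Xd)
  A21[2, ] <- A21[2, ] - colSums(res2[dep_rows] * Xd)
  A <- rbind(cbind(A11, matrix(0, p, p)), cbind(A21, A22))
  psi <- cbind(as.numeric(inval) * res1 * X1, res2 * X2)
  B <- crossprod(psi)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NA_real_)
  V <- Ainv %*% B %*% t(Ainv)
  sqrt(V[p + 2L, p + 2L])
}

rc_common <- function(cohort, sel) {
  n <- nrow(cohort)
  inval <- rep(FALSE, n); inval[sel$indices] <- TRUE
  X1 <- design_matrix(cohort$wc, cohort)
  sub <- which(inval)
  cal <- fit_linear(cohort$vat[sub], X1[sub, , drop = FALSE])
  list(inval = inval, X1 = X1, cal = cal)
}

#' Standard regression calibration
#'
#' Two-step correction: (1) fit the calibration model of the gold standard
#' on the substitute and confounders within the validation sample; (2)
#' replace the substitute by the predicted conditional mean of the gold
#' standard for every individual and fit the outcome model on the full
#' cohort. The standard error accounts for the estimated calibration
#' parameters through a stacked estimating-equation sandwich (multivariate
#' delta method).
#'
#' @inheritParams est_ivs_restricted
#' @return An `estimate_record`.
#' @export
est_standard_rc <- function(cohort, sel) {
  stopifnot(inherits(sel, "validation_selection"))
  cc <- rc_common(cohort, sel)
  if (!cc$cal$converged) return(new_record("standard_rc", sel$strategy, NA, NA, FALSE))
  pred <- drop(cc$X1 %*% cc$cal$coef)
  X2 <- design_matrix(pred, cohort)
  out <- fit_linear(cohort$ir, X2)
  if (!out$converged) return(new_record("standard_rc", sel$strategy, NA, NA, FALSE))
  res1 <- cohort$vat - pred
  res1[!cc$inval] <- 0
  res2 <- cohort$ir - drop(X2 %*% out$coef)
  se <- rc_sandwich_se(cc$X1, res1, cc$inval, X2, res2,
                       gamma_exp = out$coef[2],
                       dep_rows = rep(TRUE, nrow(cohort)))
  new_record("standard_rc", sel$strategy, out$coef[2], se,
             is.finite(se) && se > 0)
}

#' Validation regression calibration
#'
#' Like [est_standard_rc()], but individuals inside the validation sample
#' keep their observed gold-standard value; only individuals outside it
#' receive the calibration prediction (a hybrid exposure). The sandwich
#' variance propagates calibration uncertainty through the predicted rows
#' only.
#'
#' @inheritParams est_ivs_restricted
#' @return An `estimate_record`.
#' @export
est_validation_rc <- function(cohort, sel) {
  stopifnot(inherits(sel, "validation_selection"))
  cc <- rc_common(cohort, sel)
  if (!cc$cal$converged) return(new_record("validation_rc", sel$strategy, NA, NA, FALSE))
  pred <- drop(cc$X1 %*% cc$cal$coef)
  hybrid <- ifelse(cc$inval, cohort$vat, pred)
  X2 <- design_matrix(hybrid, cohort)
  out <- fit_linear(cohort$ir, X2)
  if (!out$converged) return(new_record("validation_rc", sel$strategy, NA, NA, FALSE))
  res1 <- cohort$vat - pred
  res1[!cc$inval] <- 0
  res2 <- cohort$ir - drop(X2 %*% out$coef)
  se <- rc_sandwich_se(cc$X1, res1, cc$inval, X2, res2,
                       gamma_exp = out$coef[2], dep_rows = !cc$inval)
  new_record("validation_rc", sel$strategy, out$coef[2], se,
             is.finite(se) && se > 0)
}

#' Efficient regression calibration
#'
#' Inverse-variance-weighted mean of the IVS-restricted and standard
#' regression-calibration estimates:
#' `beta = (b1/v1 + b2/v2) / (1/v1 + 1/v2)` with `v = se^2`, and pooled
#' standard error `sqrt(1 / (1/v1 + 1/v2))`. The correlation between the
#' two components is ignored, which can produce slight undercoverage.
#'
#' @param rec_restricted `estimate_record` from [est_ivs_restricted()].
#' @param rec_standard `estimate_record` from [est_standard_rc()].
#' @return An `estimate_record`.
#' @export
est_efficient_rc <- function(rec_restricted, rec_standard) {
  strategy <- rec_restricted$strategy
  if (!rec_restricted$converged || !rec_standard$converged)
    return(new_record("efficient_rc", strategy, NA, NA, FALSE))
  w1 <- 1 / rec_restricted$se^2
  w2 <- 1 / rec_standard$se^2
  beta <- (rec_restricted$beta_hat * w1 + rec_standard$beta_hat * w2) / (w1 + w2)
  new_record("efficient_rc", strategy, beta, sqrt(1 / (w1 + w2)))
}

#' Express a log-scale coefficient as a percentage difference
#'
#' For outcomes analysed on the log scale, a coefficient `b` per standard
#' deviation of exposure corresponds to a `100 * (exp(b) - 1)` percent
#' difference in the outcome.
#'
#' @param beta_hat Coefficient on the log-outcome scale.
#' @return Percentage difference in the outcome.
#' @examples
#' beta_to_percent(0.2)  # 22.14
#' @export
beta_to_percent <- function(beta_hat) 100 * (exp(beta_hat) - 1)
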