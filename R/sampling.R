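# Internal-validation sampling strategies: which rows of the cohort get the
# gold-standard measurement. All three strategies return exactly m unique
# row indices; the gold standard is then masked outside the selection.

#' Size of the internal validation sample
#'
#' Converts a validation fraction into a sample size by round-half-to-even
#' (base R [round()]), with a floor of one individual.
#'
#' @param n Cohort size.
#' @param fraction Validation fraction in (0, 1].
#' @return Integer validation-sample size `m`.
#' @examples
#' validation_size(650, 0.4)  # 260
#' validation_size(650, 0.1)  # 65
#' @export
validation_size <- function(n, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  max(1L, as.integer(round(fraction * n)))
}

new_selection <- function(strategy, indices, m) {
  structure(list(strategy = strategy,
                 indices = as.integer(indices), m = as.integer(m)),
            class = "validation_selection")
}

check_m <- function(n, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m > n)
    stop("validation size `m` must satisfy 1 <= m <= n", call. = FALSE)
}

#' Random sampling of the validation sample
#'
#' Simple random sampling without replacement: every size-`m` subset of the
#' cohort is equally likely, so each individual has inclusion probability
#' `m / n`.
#'
#' @param n Cohort size.
#' @param m Validation-sample size, at most `n`.
#' @param seed Optional seed for reproducible selection.
#' @return A `validation_selection` with fields `strategy`, `indices`, `m`.
#' @export
select_random <- function(n, m, seed = NULL) {
  check_m(n, m)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  new_selection("random", sort(sample.int(n, m)), m)
}

#' Extremes sampling of the validation sample
#'
#' Selects the `floor(m/2)` individuals with the smallest and the
#' `ceiling(m/2)` with the largest error-prone measurements (the odd
#' individual goes to the upper tail). Ties are broken by original row
#' order, so the selection is deterministic given `wc`.
#'
#' @param wc Error-prone measurements for the whole cohort.
#' @param m Validation-sample size, at most `length(wc)`.
#' @return A `validation_selection`.
#' @export
select_extremes <- function(wc, m) {
  n <- length(wc)
  check_m(n, m)
  ord <- order(wc)  # stable: ties keep original row order
  lo <- m %/% 2L
  hi <- m - lo
  idx <- c(if (lo > 0L) ord[seq_len(lo)], ord[seq.int(n - hi + 1L, n)])
  new_selection("extremes", sort(unique(idx)), m)
}

#' Stratified random sampling of the validation sample
#'
#' Divides the range of the error-prone measurements into `k` equal-width
#' strata (half-open intervals, the last closed on the right so the maximum
#' is always assigned) and draws an equal quota from each by simple random
#' sampling without replacement. The base quota is `m %/% k`, with the
#' remainder assigned to the lowest-indexed strata. Strata with fewer
#' members than their quota contribute all their members; the resulting
#' shortage is redistributed one unit at a time, round-robin over the
#' strata with remaining capacity visited in order of decreasing capacity,
#' until exactly `m` individuals are selected.
#'
#' @param wc Error-prone measurements for the whole cohort.
#' @param m Validation-sample size, at most `length(wc)`.
#' @param k Number of strata (default 10, i.e. tenths of the range).
#' @param seed Optional seed for reproducible selection.
#' @return A `validation_selection`.
#' @export
select_stratified <- function(wc, m, k = 10L, seed = NULL) {
  n <- length(wc)
  check_m(n, m)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a positive number of strata", call. = FALSE)
  k <- as.integer(k)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  rng <- range(wc)
  if (rng[1] == rng[2]) {
    stratum <- rep(1L, n)  # degenerate: all mass in one stratum
  } else {
    breaks <- seq(rng[1], rng[2], length.out = k + 1L)
    stratum <- findInterval(wc, breaks, rightmost.closed = TRUE)
  }
  counts <- tabulate(stratum, nbins = k)
  quota <- rep(m %/% k, k)
  r <- m %% k
  if (r > 0L) quota[seq_len(r)] <- quota[seq_len(r)] + 1L
  take <- pmin(quota, counts)
  deficit <- m - sum(take)
  while (deficit > 0L) {
    capacity <- counts - take
    for (j in order(capacity, decreasing = TRUE)) {
      if (deficit == 0L) break
      if (capacity[j] > 0L) {
        take[j] <- take[j] + 1L
        deficit <- deficit - 1L
      }
    }
  }
  idx <- unlist(lapply(seq_len(k), function(j) {
    members <- which(stratum == j)
    if (take[j] == 0L) return(integer(0))
    if (take[j] == length(members)) members
    else members[sample.int(length(members), take[j])]
  }), use.names = FALSE)
  new_selection("stratified", sort(idx), m)
}

#' Mask the gold standard outside the validation sample
#'
#' Returns a copy of the cohort in which `vat` is set to `NA` for every
#' row not in the selection, and `in_validation` records membership. This
#' mirrors a study in which the expensive measurement is only taken in the
#' validation subset.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param sel A `validation_selection`.
#' @return The masked cohort.
#' @export
mask_nonvalidation <- function(cohort, sel) {
  stopifnot(inherits(sel, "validation_selection"))
  n <- nrow(cohort)
  if (length(sel$indices) < 1L || any(sel$indices < 1L | sel$indices > n))
    stop("selection indices must be a non-empty subset of the cohort rows",
         call. = FALSE)
  out <- cohort
  inval <- rep(FALSE, n)
  inval[sel$indices] <- TRUE
  out$vat[!inval] <- NA_real_
  out$in_validation <- inval
  out
}

#' Apply a named sampling strategy
#'
#' Convenience dispatcher used by the simulation engine.
#'
#' @param strategy One of `"random"`, `"stratified"`, `"extremes"`.
#' @param wc Error-prone measurements.
#' @param m Validation-sample size.
#' @param seed Optional seed forwarded to the randomized strategies.
#' @return A `validation_selection`.
#' @export
select_validation <- function(strategy = c("random", "stratified", "extremes"),
                              wc, m, seed = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
         random = select_random(length(wc), m, seed = seed),
         stratified = select_stratified(wc, m, seed = seed),
         extremes = select_extremes(wc, m))
}
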