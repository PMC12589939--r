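#' Estimate the RNA limit of blank from blank replicate runs
#'
#' The limit of blank (LOB) is the highest total supporting read count
#' observed for reportable fusions across replicate runs of samples expected
#' to be fusion wild-type. A positive call then requires support strictly
#' above the LOB, i.e. `call_threshold = lob + 1` total reads. With the
#' default `statistic = "max"` the estimate is exactly the maximum blank
#' observation; a nonparametric upper percentile is available for larger
#' blank panels.
#'
#' @param blanks Tibble of blank measurements with at least a
#'   `read_support` column (typically also `sample_id`, `reagent_lot`,
#'   `replicate`, as produced by [simulate_blank_runs()]).
#' @param statistic `"max"` (default) or `"percentile"`.
#' @param percentile Upper percentile used when `statistic = "percentile"`.
#' @return A list with `lob` and `call_threshold` (integers).
#' @examples
#' blanks <- simulate_blank_runs(seed = 1)
#' estimate_lob(blanks) # lob 3, call_threshold 4
#' @export
estimate_lob <- function(blanks, statistic = c("max", "percentile"),
                         percentile = 0.95) {
  statistic <- match.arg(statistic)
  if (is.null(blanks) || nrow(blanks) == 0) {
    stop("estimate_lob() requires at least one blank measurement.",
         call. = FALSE)
  }
  if (!"read_support" %in% names(blanks)) {
    stop("`blanks` must have a `read_support` column.", call. = FALSE)
  }
  x <- blanks$read_support
  if (any(is.na(x) | x < 0)) {
    stop("Blank read supports must be non-negative.", call. = FALSE)
  }
  lob <- if (statistic == "max") {
    max(x)
  } else {
    as.integer(ceiling(stats::quantile(x, probs = percentile, type = 1)))
  }
  list(lob = as.integer(lob), call_threshold = as.integer(lob) + 1L)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The closed-form score interval: with \eqn{\hat p = k/n} and normal
#' quantile \eqn{z},
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'       {1 + z^2/n}.}
#' Unlike the Wald interval it is well behaved at \eqn{k = 0} and
#' \eqn{k = n}, which matters for near-perfect assay agreement rates.
#'
#' @param k Number of successes (`0 <= k <= n`). Vectorized.
#' @param n Number of trials (`> 0`).
#' @param conf Confidence level, default 0.95.
#' @return For scalar input, a named numeric `c(low, high)`; for vector
#'   input, a two-column matrix.
#' @examples
#' wilson_ci(168, 171) # approximately (0.9497, 0.9940)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (any(n <= 0)) stop("`n` must be positive.", call. = FALSE)
  if (any(k < 0 | k > n)) stop("`k` must satisfy 0 <= k <= n.", call. = FALSE)
  if (conf <= 0 || conf >= 1) stop("`conf` must be in (0, 1).", call. = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- cbind(low = center - half, high = center + half)
  if (length(k) == 1 && length(n) == 1) out <- out[1, ]
  out
}

#' Variant-level concordance against an orthogonal assay
#'
#' Computes true/false positives and negatives by set algebra between the
#' assay's positive calls and an orthogonal truth set over a finite call
#' universe, then positive percent agreement (PPA = TP/(TP+FN)), negative
#' percent agreement (NPA = TN/(TN+FP)) and their Wilson score intervals.
#'
#' @param calls Character vector of positive call identifiers
#'   (e.g. `"sample:variant"`).
#' @param truth Character vector of truth-set positive identifiers.
#' @param universe_size Total number of (sample, variant) opportunities;
#'   must be at least `length(union(calls, truth))`.
#' @param conf Confidence level for the intervals.
#' @return An object of class `concordance_result`: a list with `tp`, `fp`,
#'   `fn`, `tn`, `ppa`, `npa` (fractions; `NA` when undefined), `ppa_ci`,
#'   `npa_ci`.
#' @export
concordance <- function(calls, truth, universe_size, conf = 0.95) {
  calls <- unique(as.character(calls))
  truth <- unique(as.character(truth))
  n_union <- length(union(calls, truth))
  if (universe_size < n_union) {
    stop("`universe_size` must be at least |union(calls, truth)| = ",
         n_union, ".", call. = FALSE)
  }
  tp <- length(intersect(calls, truth))
  fp <- length(setdiff(calls, truth))
  fn <- length(setdiff(truth, calls))
  tn <- universe_size - tp - fp - fn
  ppa <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  npa <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  res <- list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppa = ppa, npa = npa,
    ppa_ci = if (is.na(ppa)) c(low = NA_real_, high = NA_real_) else
      wilson_ci(tp, tp + fn, conf),
    npa_ci = if (is.na(npa)) c(low = NA_real_, high = NA_real_) else
      wilson_ci(tn, tn + fp, conf),
    conf = conf
  )
  structure(res, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Concordance vs orthogonal assay\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(p, ci) {
    if (is.na(p)) return("undefined")
    sprintf("%.3f%% (%g%% CI %.2f%%-%.2f%%)", 100 * p, 100 * x$conf,
            100 * ci[["low"]], 100 * ci[["high"]])
  }
  cat("  PPA:", fmt(x$ppa, x$ppa_ci), "\n")
  cat("  NPA:", fmt(x$npa, x$npa_ci), "\n")
  invisible(x)
}
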