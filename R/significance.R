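#' Empirical p-value against a permutation null
#'
#' For each observed statistic `t`, returns
#' `p = (1 + #\{r : t0_r >= t\}) / (1 + R)`: the add-one permutation
#' p-value, with the `>=` inclusive so a statistic exactly tied with null
#' values counts them as exceedances.  The smallest attainable value is
#' `1 / (1 + R)`.  Exceedance counts are found by binary search on the
#' sorted null.
#'
#' @param t numeric vector of observed TIC_e statistics.
#' @param null a `tic_null` from [build_null()] or [load_null()].
#' @return Numeric vector of p-values in `[1/(1+R), 1]`.
#' @examples
#' null <- build_null(20, R = 199, seed = 1)
#' empirical_pvalue(max(null$t0) + 1, null)  # 1/200
#' @export
empirical_pvalue <- function(t, null) {
  if (!inherits(null, "tic_null")) stop("'null' must be a tic_null object")
  R <- null$R
  # #{t0 < t} via binary search; exceedances = R - that
  below <- findInterval(t, null$t0, left.open = TRUE)
  (1 + R - below) / (1 + R)
}

#' Estimate the null fraction pi0
#'
#' Storey estimator of the fraction of tests for which the null hypothesis
#' of independence is true, read off the flat right tail of the p-value
#' distribution: `pi0(lambda) = #\{p > lambda\} / ((1 - lambda) * M)`
#' evaluated on a grid of `lambda`, smoothed with a cubic spline (df = 3)
#' and taken at the largest `lambda` (the Storey–Tibshirani smoother).  For
#' fewer than 100 p-values the smoother is unstable and the fixed
#' `lambda = 0.5` estimate is used instead.  The result is clipped to
#' `(0, 1]`; if no p-value exceeds the largest `lambda` the estimator is
#' undefined and falls back to 1 with a warning.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid evaluation grid in `[0, 1)`; default `0, 0.05, ..., 0.95`.
#' @return `pi0`, a number in `(0, 1]`, with attribute `pi0_lambda` giving
#'   the per-lambda estimates.
#' @examples
#' estimate_pi0(runif(5000))  # ~1
#' @export
estimate_pi0 <- function(pvals, lambda_grid = seq(0, 0.95, by = 0.05)) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("'pvals' must lie in [0, 1]")
  if (any(lambda_grid < 0 | lambda_grid >= 1))
    stop("'lambda_grid' must lie in [0, 1)")
  M <- length(pvals)
  lambda_grid <- sort(unique(lambda_grid))
  pi0_l <- vapply(lambda_grid,
                  function(l) sum(pvals > l) / ((1 - l) * M), 0)
  if (sum(pvals > max(lambda_grid)) == 0) {
    # no mass beyond the grid: the tail estimate is degenerate
    warning("all p-values <= max(lambda_grid); falling back to pi0 = 1")
    pi0 <- 1
  } else if (length(lambda_grid) == 1L) {
    pi0 <- pi0_l
  } else if (M < 100) {
    l <- 0.5
    pi0 <- sum(pvals > l) / ((1 - l) * M)
  } else {
    fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda_grid))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  attr(pi0, "pi0_lambda") <- stats::setNames(pi0_l, lambda_grid)
  pi0
}

#' Storey q-values
#'
#' `q(p_i) = min over thresholds h >= p_i of pi0 * M * h / #\{p_j <= h\}`,
#' the minimum false discovery rate at which pair `i` would be called
#' significant.  Thresholds run over the distinct observed p-values, ties
#' counted inclusively; results are capped at 1 and are non-decreasing in
#' `p`.  At `pi0 = 1` this coincides with Benjamini–Hochberg adjusted
#' p-values.
#'
#' @param pvals numeric vector of p-values.
#' @param pi0 null fraction in `(0, 1]`; estimated with [estimate_pi0()]
#'   when `NULL`.
#' @return Numeric vector of q-values, same order as `pvals`, with
#'   attribute `pi0`.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.5, 0.9), pi0 = 1)  # 0.04 0.04 0.667 0.9
#' @export
storey_qvalues <- function(pvals, pi0 = NULL) {
  M <- length(pvals)
  if (M == 0L) return(numeric(0))
  if (is.null(pi0)) pi0 <- estimate_pi0(pvals)
  if (pi0 <= 0 || pi0 > 1) stop("'pi0' must be in (0, 1]")
  ord <- order(pvals)
  ps <- pvals[ord]
  # FDR(h) at h = each sorted p, ties counted inclusively
  n_le <- rank(ps, ties.method = "max")
  fdr <- pmin(as.numeric(pi0) * M * ps / n_le, 1)
  q <- rev(cummin(rev(fdr)))  # min over h >= p_i
  out <- numeric(M)
  out[ord] <- q
  attr(out, "pi0") <- as.numeric(pi0)
  out
}

#' Multiple-testing correction
#'
#' Dispatches to the chosen procedure: `"qvalue"` (Storey, FDR; the
#' default), `"bh"` / `"by"` (Benjamini–Hochberg / Benjamini–Yekutieli,
#' FDR), `"bonferroni"` and `"holm"` (FWER).  Classical procedures use
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values.
#' @param method correction method name.
#' @return Numeric vector of adjusted values in `[0, 1]`, attributes
#'   `method` and (for `"qvalue"`) `pi0`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh")
#' @export
adjust_pvalues <- function(pvals,
                           method = c("qvalue", "bh", "by", "bonferroni", "holm")) {
  if (!is.character(method))
    stop("unknown method; valid: qvalue, bh, by, bonferroni, holm")
  method <- tryCatch(match.arg(method),
                     error = function(e)
                       stop("unknown method '", method[1],
                            "'; valid: qvalue, bh, by, bonferroni, holm"))
  out <- switch(method,
    qvalue = storey_qvalues(pvals),
    bh = p.adjust(pvals, method = "BH"),
    by = p.adjust(pvals, method = "BY"),
    bonferroni = p.adjust(pvals, method = "bonferroni"),
    holm = p.adjust(pvals, method = "holm"))
  attr(out, "method") <- method
  out
}

#' Diagnostic p-value histogram
#'
#' Bin counts of the p-values on equal-width bins over `[0, 1]`.  Under the
#' composite screen the histogram should look like a spike near zero (true
#' associations) on top of a flat floor (null pairs); departures from a flat
#' right tail signal that the uniform-null assumption behind the q-value
#' machinery is violated.
#'
#' @param pvals numeric vector of p-values.
#' @param n_bins number of bins (default 20).
#' @return Integer vector of counts (summing to `length(pvals)`), with
#'   attribute `breaks`.
#' @export
pvalue_histogram <- function(pvals, n_bins = 20) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(ceiling(pvals * n_bins), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  attr(counts, "breaks") <- breaks
  counts
}
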