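#' Default grid-resolution exponent for a sample size
#'
#' The strength stage computes MIC_e with `B(n) = n^alpha`, where the
#' default exponent shrinks with the number of samples (higher resolution is
#' affordable, and equitable, only with more data).  Ranges are
#' left-closed / right-open and partition `[2, Inf)`:
#'
#' | n                  | alpha |
#' |--------------------|-------|
#' | n < 25             | 0.85  |
#' | 25 <= n < 50       | 0.80  |
#' | 50 <= n < 250      | 0.75  |
#' | 250 <= n < 500     | 0.70  |
#' | 500 <= n < 1000    | 0.65  |
#' | 1000 <= n < 2500   | 0.60  |
#' | 2500 <= n < 5000   | 0.55  |
#' | 5000 <= n < 10000  | 0.50  |
#' | 10000 <= n < 40000 | 0.45  |
#' | n >= 40000         | 0.40  |
#'
#' @param n sample count, `n >= 2`.
#' @return The default exponent `alpha`.
#' @examples
#' alpha_for_n(100)    # 0.75
#' alpha_for_n(50000)  # 0.40
#' @export
alpha_for_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2) stop("'n' must be >= 2")
  cuts <- c(25, 50, 250, 500, 1000, 2500, 5000, 10000, 40000)
  alphas <- c(0.85, 0.80, 0.75, 0.70, 0.65, 0.60, 0.55, 0.50, 0.45, 0.40)
  alphas[findInterval(n, cuts) + 1L]
}

#' MIC_e strength of the significant associations
#'
#' Annotates every pair whose adjusted value falls below `threshold` with its
#' MIC_e strength, computed at the equitability-oriented resolution
#' `B = grid_bound(n, alpha_for_n(n))` (override via `alpha`), and returns
#' them sorted by descending strength.  The stage never changes the
#' significant set — it only ranks it.
#'
#' @param pairs data frame with columns `pair_id`, `var1`, `var2`,
#'   `adjusted` (as produced by [run_pipeline()] before the strength step).
#' @param x variable-by-sample numeric matrix holding the `var1` rows.
#' @param y optional second matrix holding the `var2` rows; defaults to `x`.
#' @param threshold significance cutoff on the adjusted value (default 0.05).
#' @param alpha optional override of the [alpha_for_n()] exponent.
#' @param c clumping factor for the strength-stage estimator (default 5).
#' @return Data frame `pair_id`, `var1`, `var2`, `adjusted`, `mic_e`,
#'   descending in `mic_e`.
#' @export
strength_table <- function(pairs, x, y = NULL, threshold = 0.05,
                           alpha = NULL, c = 5) {
  if (is.null(y)) y <- x
  need <- c("pair_id", "var1", "var2", "adjusted")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns ", paste(need, collapse = ", "))
  sig <- pairs[pairs$adjusted < threshold, , drop = FALSE]
  n <- ncol(x)
  if (nrow(sig) == 0L)
    return(data.frame(pair_id = character(0), var1 = character(0),
                      var2 = character(0), adjusted = numeric(0),
                      mic_e = numeric(0)))
  i <- match(sig$var1, rownames(x))
  j <- match(sig$var2, rownames(y))
  if (anyNA(i))
    stop("pair variable not found in data: ", sig$var1[which(is.na(i))[1L]])
  if (anyNA(j))
    stop("pair variable not found in data: ", sig$var2[which(is.na(j))[1L]])
  if (is.null(alpha)) alpha <- alpha_for_n(n)
  params <- mine_params(B = grid_bound(n, alpha), c = c)
  st <- cpp_stat_batch(x, y, i, j, params$B, params$c, TRUE)
  out <- data.frame(pair_id = sig$pair_id, var1 = sig$var1, var2 = sig$var2,
                    adjusted = sig$adjusted, mic_e = st[, 2L])
  out <- out[order(-out$mic_e), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  out
}
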