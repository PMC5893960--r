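#' Estimator parameters
#'
#' Bundles the two tunables of the MIC_e / TIC_e estimators: `B`, the bound
#' on grid resolution (entries exist for all grids with `k * l <= B`,
#' `k, l >= 2`), and `c`, the clumping coarseness factor (the axis being
#' optimized is pre-coarsened to at most `c * k_max` candidate cut
#' intervals).  `B = 9` with `c = 5` is the default for the independence-test
#' (TIC_e) stage; the strength stage instead derives `B` from the sample size
#' via [grid_bound()] and [alpha_for_n()].
#'
#' @param B integer grid-resolution bound, `B >= 4`.
#' @param c integer clumping factor, `c >= 1`.
#' @return An object of class `mine_params`.
#' @examples
#' mine_params()        # B = 9, c = 5 defaults
#' mine_params(B = 12)  # for more complex alternatives
#' @export
mine_params <- function(B = 9, c = 5) {
  B <- as.integer(B)
  c <- as.integer(c)
  if (length(B) != 1L || is.na(B) || B < 4L)
    stop("'B' must be a single integer >= 4 (below 4 no 2x2 grid fits)")
  if (length(c) != 1L || is.na(c) || c < 1L)
    stop("'c' must be a single integer >= 1")
  structure(list(B = B, c = c), class = "mine_params")
}

#' @export
print.mine_params <- function(x, ...) {
  cat(sprintf("mine_params: B = %d (grid bound), c = %d (clumping factor)\n",
              x$B, x$c))
  invisible(x)
}

#' Sample-size-dependent grid-resolution bound
#'
#' Computes `B(n) = max(floor(n^alpha), b_min)`.  Used by the strength stage,
#' where the exponent `alpha` shrinks with `n` (see [alpha_for_n()]) to trade
#' resolution against variance.
#'
#' @param n sample count, `n >= 2`.
#' @param alpha exponent in `(0, 1]`.
#' @param b_min lower clamp; defaults to 4, the smallest bound admitting a
#'   2x2 grid.
#' @return Integer grid bound.
#' @examples
#' grid_bound(100, 0.75)  # 31
#' @export
grid_bound <- function(n, alpha, b_min = 4L) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("'n' must be a single sample count >= 2")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]")
  max(as.integer(floor(n^alpha)), as.integer(b_min))
}

#' Mass equipartition of one axis
#'
#' Assigns each value to one of `l` rows so that row masses are as balanced
#' as integer counts allow.  Exactly tied values always share a row (a grid
#' line can never separate them), and when `n` is not divisible by `l` the
#' extra points go to the lowest-index rows.  The assignment depends only on
#' the sort order of `values`.  With heavy ties fewer than `l` rows may be
#' occupied; this degenerate partition is returned as-is.
#'
#' @param values numeric vector.
#' @param l number of rows, `l >= 2`.
#' @return Integer vector of row indices in `1..l`, in input order.
#' @examples
#' equipartition(c(3, 1, 2, 6, 5, 4), 3)
#' equipartition(c(1, 1, 1, 2), 2)  # tied triple shares row 1
#' @export
equipartition <- function(values, l) {
  if (length(l) != 1L || is.na(l) || l < 2) stop("'l' must be >= 2")
  if (length(values) < l) stop("need at least 'l' values")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite")
  cpp_equipartition(as.numeric(values), as.integer(l))
}

#' Clump a row labelling along the other axis
#'
#' Walks the points in ascending `x` order and merges consecutive points with
#' identical row label (and all points tied on `x`) into clumps — the only
#' intervals whose boundaries can carry an optimal column cut.  If more than
#' `max_clumps` clumps arise they are greedily merged, without splitting any
#' clump, into superclumps of at least `ceiling(n / max_clumps)` points.
#'
#' @param x numeric vector (the axis to be optimized).
#' @param row_assignment integer row labels from [equipartition()] of the
#'   other axis, in the same point order as `x`.
#' @param max_clumps cap on the number of clumps, normally `c * k_max`.
#' @return Integer matrix, one row per clump in `x` order, column `r` giving
#'   the number of clump points lying in row `r`.
#' @examples
#' x <- 1:6
#' equicharclump(x, equipartition(x, 2), max_clumps = 10)  # 2 clumps
#' @export
equicharclump <- function(x, row_assignment, max_clumps) {
  if (length(x) != length(row_assignment))
    stop("'x' and 'row_assignment' lengths differ")
  l <- max(row_assignment)
  cpp_clumps(as.numeric(x), as.integer(row_assignment), as.integer(l),
             as.integer(max_clumps))
}

#' Optimal column partitions over clump prefixes
#'
#' For a fixed row labelling, computes `I*(k)`, the maximal mutual
#' information (in bits) between the row variable and any partition of the
#' `x` axis into at most `k` contiguous columns with cuts at clump
#' boundaries, for `k = 2..k_max`.  Solved by dynamic programming over clump
#' prefixes ("best solution on a prefix with one fewer column, plus a final
#' column"); `I*(k)` is non-decreasing in `k`.
#'
#' @inheritParams equicharclump
#' @param k_max largest column count, `>= 2`.
#' @param max_clumps optional clump cap; defaults to `length(x)` (no
#'   coarsening).
#' @return Named numeric vector `I*(2) .. I*(k_max)`.
#' @export
optimize_axis <- function(x, row_assignment, k_max, max_clumps = NULL) {
  if (length(k_max) != 1L || is.na(k_max) || k_max < 2)
    stop("'k_max' must be >= 2")
  if (is.null(max_clumps)) max_clumps <- length(x)
  l <- max(row_assignment)
  out <- cpp_optimize_axis(as.numeric(x), as.integer(row_assignment),
                           as.integer(l), as.integer(k_max),
                           as.integer(max_clumps))
  names(out) <- paste0("k", 2:k_max)
  out
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 5) stop("need at least 5 samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("'x' and 'y' must be finite and non-missing")
  if (var(x) == 0 || var(y) == 0)
    warning("constant vector: all characteristic-matrix entries are zero")
  invisible(NULL)
}

#' Characteristic matrix of a variable pair
#'
#' For every grid shape `(k, l)` with `k, l >= 2` and `k * l <= B`, the entry
#' is the maximal mutual information over admissible `k x l` grids — one axis
#' equipartitioned, the other optimized, the larger of the two orientations
#' kept — normalized by `log2(min(k, l))`, so every entry lies in `[0, 1]`.
#'
#' @param x,y numeric vectors of equal length `n >= 5`.
#' @param params a [mine_params()] object.
#' @return Data frame with columns `k`, `l`, `value`, one row per grid shape;
#'   attributes `n` and `params`.
#' @examples
#' x <- 1:10
#' characteristic_matrix(x, x, mine_params(B = 4))  # single entry, value 1
#' @export
characteristic_matrix <- function(x, y, params = mine_params()) {
  check_pair(x, y)
  m <- cpp_charmat(as.numeric(x), as.numeric(y), params$B, params$c)
  kl <- expand.grid(k = 2:(params$B %/% 2), l = 2:(params$B %/% 2))
  kl <- kl[kl$k * kl$l <= params$B, , drop = FALSE]
  kl <- kl[order(kl$k, kl$l), , drop = FALSE]
  out <- data.frame(k = kl$k, l = kl$l,
                    value = m[cbind(kl$k - 1L, kl$l - 1L)])
  rownames(out) <- NULL
  attr(out, "n") <- length(x)
  attr(out, "params") <- params
  out
}

#' Maximal information coefficient (MIC_e)
#'
#' The maximal entry of the characteristic matrix: a dependence strength in
#' `[0, 1]`, approximately 1 for noiseless functional relationships and near
#' 0 for independent pairs at large `n`.  Symmetric in its arguments and
#' invariant under strictly increasing transforms of either one.
#'
#' @inheritParams characteristic_matrix
#' @return A number in `[0, 1]`.
#' @examples
#' x <- runif(100)
#' mic_e(x, 3 * x + 7)   # ~1
#' @export
mic_e <- function(x, y, params = mine_params()) {
  check_pair(x, y)
  cpp_mine(as.numeric(x), as.numeric(y), params$B, params$c)$mic
}

#' Total information coefficient (TIC_e)
#'
#' The sum of all characteristic-matrix entries, bounded by the number of
#' grid shapes with `k * l <= B`.  TIC_e aggregates evidence across grid
#' resolutions, which gives it high power as an independence-test statistic;
#' it is the statistic compared against the permutation null of
#' [build_null()].
#'
#' @inheritParams characteristic_matrix
#' @return A non-negative number.
#' @export
tic_e <- function(x, y, params = mine_params()) {
  check_pair(x, y)
  cpp_mine(as.numeric(x), as.numeric(y), params$B, params$c)$tic
}
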