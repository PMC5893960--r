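#' Empirical TIC_e null distribution
#'
#' Estimates the null distribution of TIC_e for sample size `n` by computing
#' the statistic on `R` random permutations of a tie-free rank sequence.
#' Because TIC_e depends only on the rank order of its inputs, a single null
#' built this way is valid for every variable pair measured on the same `n`
#' samples with the same estimator parameters — the expensive permutation
#' stage is paid once per screen, not once per pair.  Real data with heavy
#' ties can only lower the observed statistic relative to this tie-free
#' null, so p-values are (slightly) conservative there.
#'
#' @param n sample count, `n >= 5`.
#' @param R number of permutations, `R >= 1`.  The default `2e5` gives a
#'   p-value floor of `1 / (R + 1) = 5e-6`; smaller `R` is fine for
#'   exploratory screens with few tests.
#' @param params a [mine_params()] object (default `B = 9`, `c = 5`).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the null is reproducible.  Permutations are drawn strictly
#'   sequentially from R's RNG.
#' @return An object of class `tic_null`: list with fields `n`, `R`,
#'   `params`, `seed` and `t0`, the ascending-sorted null statistics.
#' @examples
#' null <- build_null(20, R = 200, seed = 1)
#' quantile(null$t0, 0.99)
#' @export
build_null <- function(n, R = 2e5, params = mine_params(), seed = NULL) {
  n <- as.integer(n)
  R <- as.integer(R)
  if (is.na(n) || n < 5) stop("'n' must be >= 5")
  if (is.na(R) || R < 1) stop("'R' must be >= 1")
  if (!inherits(params, "mine_params")) stop("'params' must be mine_params()")
  if (!is.null(seed)) set.seed(seed)
  t0 <- sort(cpp_tic_null(n, R, params$B, params$c))
  structure(list(n = n, R = R, params = params,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 t0 = t0),
            class = "tic_null")
}

#' @export
print.tic_null <- function(x, ...) {
  cat(sprintf(
    "tic_null: n = %d, R = %d, B = %d, c = %d, seed = %s\n  t0 range [%.4g, %.4g], upper 5%% quantile %.4g\n",
    x$n, x$R, x$params$B, x$params$c,
    ifelse(is.na(x$seed), "none", as.character(x$seed)),
    min(x$t0), max(x$t0), stats::quantile(x$t0, 0.95)))
  invisible(x)
}

#' Save / load a null distribution archive
#'
#' Plain-text archive: a versioned header line carrying `(n, R, B, c, seed)`
#' followed by one null statistic per line at full precision.  A null is
#' only valid for a matching sample size and parameter set, so `load_null()`
#' can be given the expected `n` and `params` and errors on any mismatch.
#'
#' @param null a `tic_null` object.
#' @param path file path.
#' @return `save_null()` returns `path` invisibly; `load_null()` returns the
#'   restored `tic_null`.
#' @export
save_null <- function(null, path) {
  if (!inherits(null, "tic_null")) stop("'null' must be a tic_null object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#micscreen_null\tv1\tn=%d\tR=%d\tB=%d\tc=%d\tseed=%s",
                     null$n, null$R, null$params$B, null$params$c,
                     ifelse(is.na(null$seed), "NA", as.character(null$seed))),
             con)
  writeLines(sprintf("%.17g", null$t0), con)
  invisible(path)
}

#' @param n,params optional expected sample count / [mine_params()]; a
#'   mismatch with the archive header is a hard error.
#' @rdname save_null
#' @export
load_null <- function(path, n = NULL, params = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#micscreen_null\tv1"))
    stop("not a micscreen null archive: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-(1:2)]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  fields <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  hn <- as.integer(fields[["n"]])
  hR <- as.integer(fields[["R"]])
  hp <- mine_params(as.integer(fields[["B"]]), as.integer(fields[["c"]]))
  hseed <- suppressWarnings(as.integer(fields[["seed"]]))
  t0 <- as.numeric(lines[-1L])
  if (anyNA(t0)) stop("corrupt null archive (non-numeric entries): ", path)
  if (length(t0) != hR)
    stop(sprintf("truncated null archive: header says R = %d, found %d values",
                 hR, length(t0)))
  if (!is.null(n) && as.integer(n) != hn)
    stop(sprintf("null archive was built for n = %d, analysis requests n = %d",
                 hn, as.integer(n)))
  if (!is.null(params) &&
      (params$B != hp$B || params$c != hp$c))
    stop(sprintf("null archive was built with B = %d, c = %d; analysis requests B = %d, c = %d",
                 hp$B, hp$c, params$B, params$c))
  structure(list(n = hn, R = hR, params = hp, seed = hseed, t0 = t0),
            class = "tic_null")
}
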