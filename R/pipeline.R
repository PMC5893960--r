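#' Read / write a variable-by-sample matrix
#'
#' Tab-delimited text: header row of sample ids, first column of variable
#' ids, numeric cells.  Lines starting with `#` carry run metadata and are
#' skipped.  Ragged rows, duplicate ids and non-numeric cells are parse
#' errors naming the offending line / id.  By default rows with any missing
#' value are rejected: the shared permutation null is only valid for a
#' single common sample count `n`.
#'
#' @param path file path.
#' @param transpose set `TRUE` for files with samples as rows.
#' @return Numeric matrix with variable rownames and sample colnames.
#' @export
read_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged table in %s: line %d has %d fields, expected %d",
                 path, which(nf != nf[1L])[1L] + 1L,
                 nf[which(nf != nf[1L])[1L]], nf[1L]))
  d <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                  check.names = FALSE, colClasses = "character", quote = "")
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate variable id in ", path, ": ", ids[duplicated(ids)][1L])
  m <- as.matrix(d[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) & !(m %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell in %s at line %d (variable '%s'): '%s'",
                 path, bad[1L, 1L] + 1L, ids[bad[1L, 1L]],
                 m[bad[1L, 1L], bad[1L, 2L]]))
  if (anyNA(num))
    stop("missing values in ", path,
         "; rows with missing samples are not supported by the shared null")
  if (transpose) num <- t(num)
  message(sprintf("read %d variables x %d samples from %s",
                  nrow(num), ncol(num), path))
  num
}

#' @param m numeric matrix, variables as rows.
#' @param comment optional character vector written as leading `#` lines.
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("#", comment), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- cbind(rownames(m), format(m, digits = 15, trim = TRUE,
                                    scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Enumerate variable pairs for an experiment mode
#'
#' `within` tests all `M (M - 1) / 2` unordered pairs of one matrix, in
#' lexicographic row order; `cross` tests all `M x K` pairs between two
#' matrices; `rowwise` tests only `(x_i, y_i)` for `i = 1..min(M, K)`.
#'
#' @param x variable-by-sample matrix.
#' @param y second matrix (required for `cross` / `rowwise`).
#' @param mode experiment mode.
#' @return Data frame with row indices `i`, `j`, names `var1`, `var2` and a
#'   `pair_id`.
#' @examples
#' m <- matrix(0, 3, 4, dimnames = list(letters[1:3], NULL))
#' nrow(enumerate_pairs(m))  # 3
#' @export
enumerate_pairs <- function(x, y = NULL,
                            mode = c("within", "cross", "rowwise")) {
  mode <- match.arg(mode)
  M <- nrow(x)
  if (mode == "within") {
    if (M < 2) stop("'within' mode needs at least 2 variables")
    i <- rep.int(seq_len(M - 1L), (M - 1L):1L)
    j <- unlist(lapply(seq_len(M - 1L), function(a) (a + 1L):M))
    v1 <- rownames(x)[i]; v2 <- rownames(x)[j]
  } else {
    if (is.null(y)) stop("'", mode, "' mode requires a second matrix")
    if (ncol(x) != ncol(y))
      stop("sample columns differ between matrices (", ncol(x), " vs ",
           ncol(y), ")")
    K <- nrow(y)
    if (mode == "cross") {
      i <- rep(seq_len(M), each = K)
      j <- rep.int(seq_len(K), M)
    } else {
      i <- j <- seq_len(min(M, K))
    }
    v1 <- rownames(x)[i]; v2 <- rownames(y)[j]
  }
  data.frame(i = i, j = j, var1 = v1, var2 = v2,
             pair_id = paste(v1, v2, sep = "~"))
}

#' Run the four-step association screen
#'
#' Chains the full procedure on one or two matrices: (1) build (or reuse) a
#' shared TIC_e permutation null for the common sample count, (2) compute
#' the observed TIC_e of every enumerated pair and its empirical p-value,
#' (3) apply multiple-testing correction, (4) estimate MIC_e strength for
#' the pairs passing `threshold`.  Reusing a `null` requires matching `n`
#' and estimator parameters (hard error otherwise).  A warning is issued
#' when `R` is too small for any pair to reach significance after
#' correction, i.e. when `1/(1+R) > threshold / M`.
#'
#' @param x variable-by-sample numeric matrix.
#' @param y optional second matrix (same samples).
#' @param mode experiment mode, see [enumerate_pairs()].
#' @param R permutations for the null (default `2e5`).
#' @param params [mine_params()] for the test stage (default `B = 9`,
#'   `c = 5`).
#' @param method multiple-testing method, see [adjust_pvalues()].
#' @param threshold significance cutoff on the adjusted value.
#' @param alpha optional strength-stage exponent override.
#' @param seed optional RNG seed for the null stage.
#' @param null optional precomputed `tic_null` to reuse.
#' @param strength set `FALSE` to skip the MIC_e annotation step.
#' @return Data frame with one row per pair: `pair_id`, `var1`, `var2`,
#'   `tic_e`, `pval`, `adjusted` and `mic_e` (`NA` for non-significant
#'   pairs).  Attributes: `null`, `pi0` (q-value method), `method`,
#'   `params`, `threshold`.
#' @examples
#' d <- sd_generate(60, 0.1, 30, seed = 1)
#' res <- run_pipeline(d$x, d$y, mode = "rowwise", R = 500, seed = 2)
#' head(res[order(res$pval), ])
#' @export
run_pipeline <- function(x, y = NULL, mode = c("within", "cross", "rowwise"),
                         R = 2e5, params = mine_params(),
                         method = "qvalue", threshold = 0.05, alpha = NULL,
                         seed = NULL, null = NULL, strength = TRUE) {
  mode <- match.arg(mode)
  if (is.null(rownames(x))) rownames(x) <- sprintf("V%05d", seq_len(nrow(x)))
  if (!is.null(y) && is.null(rownames(y)))
    rownames(y) <- sprintf("W%05d", seq_len(nrow(y)))
  if (anyNA(x) || (!is.null(y) && anyNA(y)))
    stop("missing values are not supported (shared null requires one n)")
  pairs <- enumerate_pairs(x, y, mode)
  n <- ncol(x)
  M <- nrow(pairs)
  if (is.null(null)) {
    null <- build_null(n, R = R, params = params, seed = seed)
  } else {
    if (!inherits(null, "tic_null")) stop("'null' must be a tic_null")
    if (null$n != n)
      stop(sprintf("null was built for n = %d but data have n = %d samples",
                   null$n, n))
    if (null$params$B != params$B || null$params$c != params$c)
      stop("null parameters (B, c) do not match the requested analysis")
  }
  if (1 / (1 + null$R) > threshold / M)
    warning(sprintf(
      "p-value floor 1/(1+R) = %.3g exceeds threshold/M = %.3g: permutation resolution is coarse for this many tests; consider increasing R",
      1 / (1 + null$R), threshold / M))
  ymat <- if (is.null(y)) x else y
  st <- cpp_stat_batch(x, ymat, pairs$i, pairs$j, params$B, params$c, FALSE)
  tic <- st[, 1L]
  pval <- empirical_pvalue(tic, null)
  adjusted <- adjust_pvalues(pval, method = method)
  res <- data.frame(pair_id = pairs$pair_id, var1 = pairs$var1,
                    var2 = pairs$var2, tic_e = tic, pval = pval,
                    adjusted = as.numeric(adjusted), mic_e = NA_real_)
  if (strength) {
    stab <- strength_table(res, x, ymat, threshold = threshold,
                           alpha = alpha, c = params$c)
    res$mic_e[match(stab$pair_id, res$pair_id)] <- stab$mic_e
  }
  attr(res, "null") <- null
  attr(res, "pi0") <- attr(adjusted, "pi0")
  attr(res, "method") <- attr(adjusted, "method")
  attr(res, "params") <- params
  attr(res, "threshold") <- threshold
  res
}

#' Stratified (per-class) screening
#'
#' Runs [run_pipeline()] independently within each sample class; each class
#' gets its own permutation null at its own sample count.  Classes with
#' fewer than `min_class_size` samples are skipped with a warning.
#'
#' @param x,y data matrices as in [run_pipeline()].
#' @param classes per-sample class labels (length `ncol(x)`).
#' @param ... passed on to [run_pipeline()].
#' @param min_class_size smallest analyzable class (default 5).
#' @return Named list of per-class association tables.
#' @export
stratified_run <- function(x, y = NULL, classes, ..., min_class_size = 5) {
  if (length(classes) != ncol(x))
    stop("'classes' must label every sample (length ", ncol(x), ")")
  if (anyNA(classes)) stop("'classes' must label every sample (NA found)")
  out <- list()
  for (cl in unique(as.character(classes))) {
    idx <- which(as.character(classes) == cl)
    if (length(idx) < min_class_size) {
      warning(sprintf("class '%s' has %d < %d samples; skipped",
                      cl, length(idx), min_class_size))
      next
    }
    out[[cl]] <- run_pipeline(x[, idx, drop = FALSE],
                              if (is.null(y)) NULL else y[, idx, drop = FALSE],
                              ...)
  }
  out
}

#' Write an association table as TSV
#'
#' @param res association table from [run_pipeline()].
#' @param path output path.
#' @param comment optional `#` header lines (e.g. the parameter set).
#' @return `path`, invisibly.
#' @export
write_association_table <- function(res, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("#", comment), con)
  close(con)
  suppressWarnings(
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = !is.null(comment)))
  invisible(path)
}
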