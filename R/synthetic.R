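#' Noise-intensity pool for functional benchmark pairs
#'
#' The 18,000 candidate values of the noise intensity factor `k_eta`: three
#' concatenated half-open arithmetic sequences, `[0.05, 1)` in steps of
#' 1e-4 (9,500 values), `[1, 2)` in steps of 2e-4 (5,000) and `[2, 9)` in
#' steps of 2e-3 (3,500).  Sampling `k_eta` from this pool makes the
#' realized signal share `R^2` of the dependent pairs span approximately
#' `(0, 1)`.
#'
#' @return Numeric vector of length 18,000.
#' @export
noise_pool <- function() {
  c(0.05 + 1e-4 * 0:9499,
    1 + 2e-4 * 0:4999,
    2 + 2e-3 * 0:3499)
}

sd_function_names <- c("cubic", "exponential", "line", "parabola",
                       "sigmoid", "spike")

#' Functional association forms
#'
#' The six noiseless forms used for dependent benchmark pairs, all defined
#' on `x` in `[0, 1]`: `line` is the identity, `parabola` is
#' `4 (x - 1/2)^2`, `cubic` is the third Chebyshev polynomial rescaled to
#' the unit interval (`T3(2x - 1)`), `exponential` is `2^x`, `sigmoid` is a
#' steep logistic centered at 1/2, and `spike` rises linearly to 1 at
#' `x = 0.05`, drops to 0.1 at `x = 0.1` and decays linearly to 0 at
#' `x = 1`.  Downstream statistics are rank-based in `x`, so any
#' shape-equivalent parametrization would screen identically.
#'
#' @param f_name one of `"cubic"`, `"exponential"`, `"line"`, `"parabola"`,
#'   `"sigmoid"`, `"spike"`.
#' @param x numeric vector in `[0, 1]`.
#' @return `f(x)`.
#' @examples
#' eval_function("exponential", 1)  # 2
#' @export
eval_function <- function(f_name, x) {
  switch(as.character(f_name),
    line = x,
    parabola = 4 * (x - 0.5)^2,
    cubic = { u <- 2 * x - 1; 4 * u^3 - 3 * u },
    exponential = 2^x,
    sigmoid = 1 / (1 + exp(-20 * (x - 0.5))),
    spike = ifelse(x <= 0.05, x / 0.05,
            ifelse(x <= 0.1, 1 - 0.9 * (x - 0.05) / 0.05,
                   0.1 * (1 - x) / 0.9)),
    stop("unknown function name: ", f_name,
         " (valid: ", paste(sd_function_names, collapse = ", "), ")"))
}

#' Generate a functional-association benchmark (SD1/SD2 style)
#'
#' Builds `n_pairs` variable pairs, a fraction `effect_chance` of which are
#' truly dependent: `X ~ U(0,1)` and `Y = f(X) + eta` with `f` drawn
#' uniformly from the six forms of [eval_function()] and
#' `eta = k_eta * U(-1/2, 1/2) * (max f(X) - min f(X))`, `k_eta` drawn from
#' [noise_pool()].  The zero-centered uniform keeps `E[eta] = 0` while the
#' noise amplitude scales with the realized range of `f`.  The remaining
#' pairs are i.i.d. `U(0,1)` on both coordinates.  Pair positions are
#' shuffled.  The classic configurations are 60,000 pairs at 1% effect
#' chance (with `n_samples` varied) and 60,000 pairs at `n_samples = 100`
#' (with the effect chance varied).
#'
#' @param n_pairs total number of variable pairs.
#' @param effect_chance fraction of dependent pairs in `(0, 1]`;
#'   `n_pairs * effect_chance` must be an integer.
#' @param n_samples samples per variable.
#' @param seed optional RNG seed.
#' @return List with `x`, `y` (`n_pairs x n_samples` matrices, rows
#'   `X_...` / `Y_...`, pair `i` = row `i` of each) and `truth`, a data
#'   frame with `pair_id`, `var1`, `var2`, `is_dependent`, `f_name`,
#'   `k_eta` and the realized signal share `r2 = Var(f(X)) / Var(Y)`
#'   (clamped to `[0, 1]`; `NA` for null pairs).
#' @examples
#' d <- sd_generate(100, 0.05, 50, seed = 1)
#' table(d$truth$is_dependent)
#' @export
sd_generate <- function(n_pairs = 60000, effect_chance = 0.01,
                        n_samples = 100, seed = NULL) {
  if (effect_chance <= 0 || effect_chance > 1)
    stop("'effect_chance' must be in (0, 1]")
  n_dep_real <- n_pairs * effect_chance
  n_dep <- round(n_dep_real)
  if (abs(n_dep_real - n_dep) > 1e-9)
    stop("n_pairs * effect_chance must be an integer (got ",
         format(n_dep_real), ")")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(runif(n_pairs * n_samples), nrow = n_pairs)
  Y <- matrix(runif(n_pairs * n_samples), nrow = n_pairs)
  dep <- sort(sample.int(n_pairs, n_dep))
  f_name <- rep(NA_character_, n_pairs)
  k_eta <- rep(NA_real_, n_pairs)
  r2 <- rep(NA_real_, n_pairs)
  if (n_dep > 0) {
    f_name[dep] <- sample(sd_function_names, n_dep, replace = TRUE)
    k_eta[dep] <- sample(noise_pool(), n_dep, replace = TRUE)
    for (i in dep) {
      f <- eval_function(f_name[i], X[i, ])
      eta <- k_eta[i] * runif(n_samples, -0.5, 0.5) * (max(f) - min(f))
      Y[i, ] <- f + eta
      r2[i] <- min(max(var(f) / var(Y[i, ]), 0), 1)
    }
  }
  rn_x <- sprintf("X_%05d", seq_len(n_pairs))
  rn_y <- sprintf("Y_%05d", seq_len(n_pairs))
  cn <- sprintf("S_%04d", seq_len(n_samples))
  dimnames(X) <- list(rn_x, cn)
  dimnames(Y) <- list(rn_y, cn)
  is_dep <- logical(n_pairs)
  is_dep[dep] <- TRUE
  truth <- data.frame(pair_id = paste(rn_x, rn_y, sep = "~"),
                      var1 = rn_x, var2 = rn_y,
                      is_dependent = is_dep, f_name = f_name,
                      k_eta = k_eta, r2 = r2)
  list(x = X, y = Y, truth = truth)
}

#' Generate a cluster-structured classification benchmark (Madelon style)
#'
#' A 200-variable dataset whose dependence structure is driven by clusters
#' rather than functions: samples are split evenly over 4 Gaussian clusters
#' (`sigma = 1`), two per class, centered on 4 vertices (in Gray-code
#' order) of the hypercube `\{-2, 2\}^5`.  The 5 hypercube coordinates are
#' the "informative" variables; 15 "redundant" variables are random linear
#' combinations (coefficients `U(-1, 1)`) of the informative ones; 180
#' "random" variables are i.i.d. `N(0, 1)` and independent of everything.
#' All `choose(20, 2) = 190` pairs among the 20 non-random variables are
#' truly dependent, out of `choose(200, 2) = 19,900` testable pairs.
#'
#' @param n_samples number of samples, `>= 8` (at least 2 per cluster).
#' @param seed optional RNG seed.
#' @return List with `data` (200 x `n_samples` matrix, rows `inf_*`,
#'   `red_*`, `rnd_*`), `classes` and `clusters` (per-sample labels, kept
#'   for stratified analyses; the screen itself is unsupervised), `coef`
#'   (the 15 x 5 redundant-mixing matrix) and `truth` covering all 19,900
#'   pairs with `is_dependent` and a `relation` tag
#'   (informative-informative / informative-redundant /
#'   redundant-redundant / null).
#' @export
madelon_generate <- function(n_samples, seed = NULL) {
  if (n_samples < 8) stop("'n_samples' must be >= 8 (2 per cluster)")
  if (!is.null(seed)) set.seed(seed)
  # first 4 Gray-code vertices of {-2, 2}^5: 00000 00001 00011 00010
  centers <- rbind(c(-2, -2, -2, -2, -2),
                   c(-2, -2, -2, -2,  2),
                   c(-2, -2, -2,  2,  2),
                   c(-2, -2, -2,  2, -2))
  sizes <- n_samples %/% 4L + (seq_len(4L) <= n_samples %% 4L)
  clusters <- rep(1:4, times = sizes)
  classes <- c(0L, 1L, 0L, 1L)[clusters]  # two clusters per class
  informative <- t(centers[clusters, , drop = FALSE]) +
    matrix(rnorm(5 * n_samples), nrow = 5)
  coef <- matrix(runif(15 * 5, -1, 1), nrow = 15)
  redundant <- coef %*% informative
  random <- matrix(rnorm(180 * n_samples), nrow = 180)
  data <- rbind(informative, redundant, random)
  rownames(data) <- c(sprintf("inf_%02d", 1:5), sprintf("red_%02d", 1:15),
                      sprintf("rnd_%03d", 1:180))
  colnames(data) <- sprintf("S_%04d", seq_len(n_samples))
  pairs <- which(upper.tri(diag(200)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  i <- pairs[, 1L]; j <- pairs[, 2L]
  rel <- ifelse(j <= 5, "informative-informative",
         ifelse(i <= 5 & j <= 20, "informative-redundant",
         ifelse(j <= 20, "redundant-redundant", "null")))
  truth <- data.frame(
    pair_id = paste(rownames(data)[i], rownames(data)[j], sep = "~"),
    var1 = rownames(data)[i], var2 = rownames(data)[j],
    is_dependent = j <= 20, relation = rel)
  list(data = data, classes = classes, clusters = clusters,
       coef = coef, truth = truth)
}

#' Score a screen against generator truth
#'
#' Compares the significant set (adjusted value below `threshold`) with the
#' ground-truth dependence labels.  Power (recall) is `TP / #dependent`;
#' the observed false discovery rate is `FP / max(TP + FP, 1)`, so an empty
#' call set scores `fdr = 0`.
#'
#' @param results data frame with `pair_id` and `adjusted` columns (e.g.
#'   from [run_pipeline()]).
#' @param truth data frame with `pair_id` and `is_dependent` columns (from
#'   [sd_generate()] or [madelon_generate()]).
#' @param threshold significance cutoff (default 0.05).
#' @return List with `power`, `fp_count`, `fdr`, `fn_count`.
#' @export
score_detection <- function(results, truth, threshold = 0.05) {
  if (!setequal(results$pair_id, truth$pair_id) ||
      nrow(results) != nrow(truth))
    stop("'results' and 'truth' must cover identical pair ids")
  dep <- truth$is_dependent[match(results$pair_id, truth$pair_id)]
  sig <- results$adjusted < threshold
  tp <- sum(sig & dep)
  fp <- sum(sig & !dep)
  list(power = tp / sum(dep),
       fp_count = fp,
       fdr = fp / max(tp + fp, 1),
       fn_count = sum(dep) - tp)
}
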