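# Exhaustive reference implementation of the MIC_e/TIC_e characteristic
# matrix for tiny inputs, written independently of the package's C++ path:
# plain R, enumeration over every admissible column partition instead of
# clumping + dynamic programming.  Feasible for n <= ~12, B <= 8.

oracle_mi <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  sum(ifelse(p > 0, p * log2(p / e), 0))
}

# mass equipartition: ties share a row, remainder to the lowest-index rows
oracle_equip <- function(v, l) {
  n <- length(v)
  sizes <- rep(n %/% l, l) + (seq_len(l) <= n %% l)
  targets <- cumsum(sizes)
  ord <- order(v)
  row <- integer(n)
  r <- 1L
  cnt <- 0L
  for (val in unique(v[ord])) {
    hit <- which(v == val)
    row[hit] <- r
    cnt <- cnt + length(hit)
    while (r < l && cnt >= targets[r]) r <- r + 1L
  }
  row
}

# max MI between a row labelling and any partition of x into <= k contiguous
# columns whose cuts fall between distinct x values, by full enumeration
oracle_istar <- function(x, rows, k) {
  ord <- order(x)
  xs <- x[ord]
  rs <- rows[ord]
  n <- length(x)
  gaps <- which(diff(xs) > 0)  # a cut after sorted position g
  best <- 0
  for (t in 0:min(k - 1L, length(gaps))) {
    cuts_list <- if (t == 0) list(integer(0)) else
      lapply(asplit(utils::combn(length(gaps), t), 2), function(s) gaps[s])
    for (cuts in cuts_list) {
      col <- findInterval(seq_len(n), sort(cuts) + 0.5) + 1L
      best <- max(best, oracle_mi(table(factor(col, levels = 1:(t + 1)),
                                        factor(rs, levels = sort(unique(rs))))))
    }
  }
  best
}

oracle_charmat <- function(x, y, B) {
  out <- NULL
  for (k in 2:(B %/% 2)) for (l in 2:(B %/% 2)) {
    if (k * l > B) next
    o1 <- oracle_istar(x, oracle_equip(y, l), k)  # rows on y, columns on x
    o2 <- oracle_istar(y, oracle_equip(x, k), l)  # rows on x, columns on y
    out <- rbind(out, data.frame(k = k, l = l,
                                 value = max(o1, o2) / log2(min(k, l))))
  }
  out[order(out$k, out$l), ]
}

oracle_mic <- function(x, y, B) max(oracle_charmat(x, y, B)$value)
oracle_tic <- function(x, y, B) sum(oracle_charmat(x, y, B)$value)
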