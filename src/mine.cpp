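// MIC_e / TIC_e kernel.
//
// For a pair of real vectors the characteristic matrix holds, for every grid
// shape (k columns, l rows) with k,l >= 2 and k*l <= B, the maximal mutual
// information over admissible k x l grids, normalized by log2(min(k,l)).
// Following the efficient-estimator construction, one axis is mass
// equipartitioned and the other is optimized by dynamic programming over
// clump boundaries (EQUICHARCLUMP with coarseness factor c); the larger of
// the two orientations is kept.  MIC_e is the maximal entry, TIC_e the sum
// of all entries.
//
// Hot path: a screen evaluates the statistic a few hundred thousand times
// (R permutations for the null plus every observed pair), so the per-call
// work is flattened into reusable buffers and each axis is sorted once per
// pair.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double LN2 = 0.6931471805599453;

// p * log2(p) with 0 log 0 := 0
static inline double xlog2(double p) {
  return p > 0.0 ? p * std::log(p) / LN2 : 0.0;
}

// stable ascending order (0-based indices)
static void order_of(const std::vector<double>& v, std::vector<int>& idx) {
  idx.resize(v.size());
  for (size_t i = 0; i < v.size(); ++i) idx[i] = static_cast<int>(i);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
}

// Mass equipartition into l rows given the sort order; 0-based labels in
// original point order.  Tied values always share a row; when n is not
// divisible by l the extra points go to the lowest-index rows.
static void equipartition_ord(const std::vector<double>& v,
                              const std::vector<int>& idx, int l,
                              std::vector<int>& row) {
  const int n = static_cast<int>(v.size());
  row.resize(n);
  const int base = n / l, rem = n % l;
  int r = 0, cnt = 0, i = 0;
  int target = base + (0 < rem ? 1 : 0);
  while (i < n) {
    int j = i;
    while (j < n && v[idx[j]] == v[idx[i]]) ++j;  // tie group [i, j)
    for (int t = i; t < j; ++t) row[idx[t]] = r;
    cnt += j - i;
    while (r < l - 1 && cnt >= target) {
      ++r;
      target += base + (r < rem ? 1 : 0);
    }
    i = j;
  }
}

// Workspace reused across calls (R is single-threaded).
struct MineWs {
  std::vector<int> ord1, ord2, row, ccnt, scnt, cum;
  std::vector<double> prev, curv, best;
};
static MineWs ws;

// Clump building along the free axis: points tied on the free axis form an
// atom (a cut can never fall inside one); consecutive atoms pure in the
// same row merge into a clump.  If more than max_clumps clumps arise they
// are greedily merged, without splitting any clump, into superclumps of at
// least ceil(n / max_clumps) points.  Row counts land flattened in
// ws.ccnt (m x l, row-major); returns m.
static int build_clumps(const std::vector<double>& free_v,
                        const std::vector<int>& ord,
                        const std::vector<int>& row,
                        int l, int max_clumps) {
  const int n = static_cast<int>(free_v.size());
  std::vector<int>& cc = ws.ccnt;
  cc.clear();
  int m = 0;
  int cur_pure = -2;  // -2 none yet, -1 mixed, >= 0 pure row id
  for (int i = 0; i < n;) {
    int j = i;
    while (j < n && free_v[ord[j]] == free_v[ord[i]]) ++j;  // atom [i, j)
    const int arow = row[ord[i]];
    bool pure = true;
    for (int t = i + 1; t < j; ++t)
      if (row[ord[t]] != arow) { pure = false; break; }
    if (!(cur_pure >= 0 && pure && arow == cur_pure)) {
      cc.resize(static_cast<size_t>(m + 1) * l, 0);
      ++m;
      cur_pure = pure ? arow : -1;
    }
    int* cl = &cc[static_cast<size_t>(m - 1) * l];
    for (int t = i; t < j; ++t) cl[row[ord[t]]] += 1;
    i = j;
  }
  if (m > max_clumps) {
    const int target = (n + max_clumps - 1) / max_clumps;
    std::vector<int>& sc = ws.scnt;
    sc.clear();
    int ms = 0, acc = 0;
    for (int q = 0; q < m; ++q) {
      if (acc == 0) {
        sc.resize(static_cast<size_t>(ms + 1) * l, 0);
        ++ms;
      }
      int* dst = &sc[static_cast<size_t>(ms - 1) * l];
      const int* src = &cc[static_cast<size_t>(q) * l];
      for (int r = 0; r < l; ++r) {
        dst[r] += src[r];
        acc += src[r];
      }
      if (acc >= target) acc = 0;
    }
    cc.assign(sc.begin(), sc.end());
    m = ms;
  }
  return m;
}

// Dynamic program over clump prefixes.  Mutual information of a column
// partition decomposes as H(row) + sum over columns of
//   sum_r p_{c,r} log2 p_{c,r} - p_c log2 p_c,
// so the optimum over <= t contiguous columns is an additive prefix DP.
// Fills istar[k] (k = 2..kmax) with the max MI in bits over <= k columns;
// ws.ccnt (m x l) holds the clump row counts.
static void axis_optimize(int m, int l, int n, int kmax, double* istar) {
  std::vector<int>& cum = ws.cum;
  cum.assign(static_cast<size_t>(m + 1) * l, 0);
  for (int i = 0; i < m; ++i)
    for (int r = 0; r < l; ++r)
      cum[static_cast<size_t>(i + 1) * l + r] =
          cum[static_cast<size_t>(i) * l + r] +
          ws.ccnt[static_cast<size_t>(i) * l + r];
  double hrow = 0.0;
  for (int r = 0; r < l; ++r)
    hrow -= xlog2(static_cast<double>(cum[static_cast<size_t>(m) * l + r]) / n);

  auto score = [&](int j, int i) {  // column formed by clumps (j, i]
    const int* ci = &cum[static_cast<size_t>(i) * l];
    const int* cj = &cum[static_cast<size_t>(j) * l];
    double s = 0.0;
    int tot = 0;
    for (int r = 0; r < l; ++r) {
      const int cnt = ci[r] - cj[r];
      tot += cnt;
      s += xlog2(static_cast<double>(cnt) / n);
    }
    return s - xlog2(static_cast<double>(tot) / n);
  };

  std::vector<double>& prev = ws.prev;
  std::vector<double>& curv = ws.curv;
  std::vector<double>& best = ws.best;
  prev.assign(m + 1, -1e300);
  curv.assign(m + 1, -1e300);
  best.assign(kmax + 1, -1e300);
  for (int i = 1; i <= m; ++i) prev[i] = score(0, i);
  best[1] = prev[m];  // single column: MI = 0 once hrow is added back
  for (int t = 2; t <= kmax; ++t) {
    for (int i = t; i <= m; ++i) {
      double b = -1e300;
      for (int j = t - 1; j < i; ++j) {
        const double v = prev[j] + score(j, i);
        if (v > b) b = v;
      }
      curv[i] = b;
    }
    best[t] = (m >= t) ? curv[m] : best[t - 1];
    std::swap(prev, curv);
  }
  double run = best[1];
  for (int k = 2; k <= kmax; ++k) {
    if (best[k] > run) run = best[k];
    const double v = hrow + run;
    istar[k] = v > 0.0 ? v : 0.0;
  }
}

// One orientation: equipartition `fixed_v` into l rows (l = 2..B/2) and
// optimize `free_v` into <= k columns (k = 2..B/l).  S[l][k] = max MI, bits.
static void oriented_pass(const std::vector<double>& free_v,
                          const std::vector<int>& ord_free,
                          const std::vector<double>& fixed_v,
                          const std::vector<int>& ord_fixed,
                          int B, int c,
                          std::vector< std::vector<double> >& S) {
  const int n = static_cast<int>(free_v.size());
  const int lmax = B / 2;
  S.assign(lmax + 1, std::vector<double>());
  for (int l = 2; l <= lmax; ++l) {
    const int kmax = B / l;
    if (kmax < 2) continue;
    equipartition_ord(fixed_v, ord_fixed, l, ws.row);
    const int max_clumps = std::max(2, c * kmax);
    const int m = build_clumps(free_v, ord_free, ws.row, l, max_clumps);
    S[l].assign(kmax + 1, 0.0);
    axis_optimize(m, l, n, kmax, S[l].data());
  }
}

// Full characteristic matrix, entries M[k][l] for k,l >= 2, k*l <= B;
// invalid cells are -1.
static void charmat_core(const std::vector<double>& x,
                         const std::vector<double>& y,
                         int B, int c,
                         std::vector< std::vector<double> >& M) {
  order_of(x, ws.ord1);
  order_of(y, ws.ord2);
  std::vector< std::vector<double> > S1, S2;
  oriented_pass(x, ws.ord1, y, ws.ord2, B, c, S1);  // rows on y, cols on x
  oriented_pass(y, ws.ord2, x, ws.ord1, B, c, S2);  // rows on x, cols on y
  const int kl = B / 2;
  M.assign(kl + 1, std::vector<double>(kl + 1, -1.0));
  for (int k = 2; k <= kl; ++k) {
    for (int l = 2; l * k <= B; ++l) {
      const double a = S1[l][k];
      const double b = S2[k][l];
      double v = (a > b ? a : b) /
                 (std::log(static_cast<double>(std::min(k, l))) / LN2);
      if (v > 1.0) v = 1.0;
      if (v < 0.0) v = 0.0;
      M[k][l] = v;
    }
  }
}

static void mine_pair(const std::vector<double>& x,
                      const std::vector<double>& y,
                      int B, int c, double& mic, double& tic) {
  std::vector< std::vector<double> > M;
  charmat_core(x, y, B, c, M);
  mic = 0.0;
  tic = 0.0;
  for (size_t k = 2; k < M.size(); ++k)
    for (size_t l = 2; l < M[k].size(); ++l)
      if (M[k][l] >= 0.0) {
        tic += M[k][l];
        if (M[k][l] > mic) mic = M[k][l];
      }
}

static std::vector<double> as_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
IntegerVector cpp_equipartition(NumericVector values, int l) {
  std::vector<double> v = as_vec(values);
  std::vector<int> idx, row;
  order_of(v, idx);
  equipartition_ord(v, idx, l, row);
  IntegerVector out(row.size());
  for (size_t i = 0; i < row.size(); ++i) out[i] = row[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_clumps(NumericVector x, IntegerVector rows, int l,
                         int max_clumps) {
  std::vector<double> v = as_vec(x);
  std::vector<int> row(rows.size()), idx;
  for (int i = 0; i < rows.size(); ++i) row[i] = rows[i] - 1;
  order_of(v, idx);
  const int m = build_clumps(v, idx, row, l, max_clumps);
  IntegerMatrix out(m, l);
  for (int i = 0; i < m; ++i)
    for (int r = 0; r < l; ++r)
      out(i, r) = ws.ccnt[static_cast<size_t>(i) * l + r];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_optimize_axis(NumericVector x, IntegerVector rows, int l,
                                int kmax, int max_clumps) {
  std::vector<double> v = as_vec(x);
  std::vector<int> row(rows.size()), idx;
  for (int i = 0; i < rows.size(); ++i) row[i] = rows[i] - 1;
  order_of(v, idx);
  const int m = build_clumps(v, idx, row, l, max_clumps);
  std::vector<double> istar(kmax + 1, 0.0);
  axis_optimize(m, l, static_cast<int>(x.size()), kmax, istar.data());
  NumericVector out(kmax - 1);
  for (int k = 2; k <= kmax; ++k) out[k - 2] = istar[k];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_charmat(NumericVector x, NumericVector y, int B, int c) {
  std::vector< std::vector<double> > M;
  charmat_core(as_vec(x), as_vec(y), B, c, M);
  const int kl = B / 2;
  NumericMatrix out(kl - 1, kl - 1);  // row k = 2..B/2, col l = 2..B/2
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int k = 2; k <= kl; ++k)
    for (int l = 2; l <= kl; ++l)
      if (k * l <= B) out(k - 2, l - 2) = M[k][l];
  return out;
}

// [[Rcpp::export]]
List cpp_mine(NumericVector x, NumericVector y, int B, int c) {
  double mic, tic;
  mine_pair(as_vec(x), as_vec(y), B, c, mic, tic);
  return List::create(_["mic"] = mic, _["tic"] = tic);
}

// Null TIC_e statistics: x is the identity rank sequence 1..n, y an
// independent uniform permutation drawn from R's RNG (so set.seed() in R
// governs reproducibility; draws are strictly sequential).
// [[Rcpp::export]]
NumericVector cpp_tic_null(int n, int R, int B, int c) {
  NumericVector out(R);
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) x[i] = i + 1;
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) y[i] = i + 1;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    double mic, tic;
    mine_pair(x, y, B, c, mic, tic);
    out[r] = tic;
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch statistics for pairs (ii[p]-th row of X, jj[p]-th row of Y);
// returns columns tic [, mic].
// [[Rcpp::export]]
NumericMatrix cpp_stat_batch(NumericMatrix X, NumericMatrix Y,
                             IntegerVector ii, IntegerVector jj,
                             int B, int c, bool want_mic) {
  const int np = ii.size();
  const int n = X.ncol();
  NumericMatrix out(np, want_mic ? 2 : 1);
  std::vector<double> x(n), y(n);
  for (int p = 0; p < np; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    for (int s = 0; s < n; ++s) {
      x[s] = X(a, s);
      y[s] = Y(b, s);
    }
    double mic, tic;
    mine_pair(x, y, B, c, mic, tic);
    out(p, 0) = tic;
    if (want_mic) out(p, 1) = mic;
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
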