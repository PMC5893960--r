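test_that("grid_bound follows floor(n^alpha) with the b_min clamp", {
  expect_identical(grid_bound(100, 0.75), 31L)
  expect_identical(grid_bound(10000, 0.50), 100L)
  expect_identical(grid_bound(2, 0.85), 4L)  # floor(2^0.85) = 1, clamped
  expect_error(grid_bound(1, 0.5), "must be")
  expect_error(grid_bound(100, 1.5), "alpha")
})

test_that("equipartition balances mass, keeps ties whole, favours low rows", {
  expect_equal(as.integer(table(equipartition(c(10, 2, 7, 1, 9, 4), 3))),
               c(2L, 2L, 2L))
  # remainder goes to the lowest-index rows: sizes 4, 3, 3
  expect_equal(as.integer(table(equipartition(1:10, 3))), c(4L, 3L, 3L))
  # tied values are never split
  r <- equipartition(c(1, 1, 1, 2), 2)
  expect_equal(r, c(1L, 1L, 1L, 2L))
  # assignment depends only on sort order
  v <- c(5, 1, 3, 9, 7, 2, 8, 4, 6, 10)
  expect_identical(equipartition(v, 4), equipartition(rank(v), 4))
})

test_that("equicharclump merges monotone runs and caps clump counts", {
  x <- 1:6
  cl <- equicharclump(x, equipartition(x, 2), max_clumps = 10)
  expect_identical(nrow(cl), 2L)            # one clump per row
  expect_equal(rowSums(cl), c(3, 3))
  # 8 points alternating rows, capped at 4 -> 4 superclumps of 2 points
  rows <- rep(c(1L, 2L), 4)
  sc <- equicharclump(1:8, rows, max_clumps = 4)
  expect_identical(nrow(sc), 4L)
  expect_equal(unname(rowSums(sc)), rep(2, 4))
  # cap above the natural clump count is a no-op
  expect_identical(equicharclump(1:8, rows, max_clumps = 8),
                   equicharclump(1:8, rows, max_clumps = 100))
  expect_identical(nrow(equicharclump(1:8, rows, max_clumps = 100)), 8L)
})

test_that("optimize_axis reproduces deterministic and independent cases", {
  # perfectly monotone pair, 2 rows: columns reproduce rows, I*(k) = H(row)
  x <- 1:9
  rows <- equipartition(x, 2)
  h <- -sum(table(rows) / 9 * log2(table(rows) / 9))
  expect_equal(unname(optimize_axis(x, rows, k_max = 4)),
               rep(h, 3), tolerance = 1e-12)
  # when every admissible column has the marginal row mix, counts factorize
  # and the maximal MI is exactly zero: x-tied blocks each holding one point
  # of every row leave no informative cut
  x0 <- rep(1:4, each = 2)
  rows0 <- rep(c(1L, 2L), 4)
  expect_equal(unname(optimize_axis(x0, rows0, k_max = 3)), c(0, 0))
  expect_error(optimize_axis(x0, rows0, k_max = 1), "k_max")
})

test_that("optimize_axis equals exhaustive enumeration and is monotone in k", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(6:9, 1)
    x <- runif(n)
    rows <- equipartition(runif(n), 2)
    ik <- optimize_axis(x, rows, k_max = 3)
    for (k in 2:3)
      expect_equal(unname(ik[k - 1]), oracle_istar(x, rows, k),
                   tolerance = 1e-12)
    expect_true(all(diff(ik) >= -1e-15))
  }
})

test_that("characteristic matrix has the exact entry set with entries in [0,1]", {
  x <- 1:10
  cm <- characteristic_matrix(x, x, mine_params(B = 4))
  expect_identical(nrow(cm), 1L)
  expect_equal(cm$value, 1.0)  # noiseless monotone saturates M_{2,2}
  cm9 <- characteristic_matrix(runif(30), runif(30), mine_params(B = 9))
  expect_identical(cm9[, c("k", "l")],
                   data.frame(k = c(2L, 2L, 2L, 3L, 3L, 4L),
                              l = c(2L, 3L, 4L, 2L, 3L, 2L)))
  expect_true(all(cm9$value >= 0 & cm9$value <= 1))
})

test_that("degenerate inputs: constant vectors give all-zero entries", {
  x <- runif(20)
  expect_warning(cm <- characteristic_matrix(x, rep(1, 20)), "constant")
  expect_true(all(cm$value == 0))
  expect_warning(expect_equal(tic_e(x, rep(2, 20)), 0), "constant")
  expect_error(characteristic_matrix(c(x, NA), c(runif(20), 1)), "finite")
  expect_error(mic_e(1:3, 1:3), "at least 5")
})

test_that("mic_e and tic_e match exhaustive grid search on small instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    B <- sample(c(4, 6, 8), 1)
    x <- if (rep %% 3 == 0) sample(1:4, n, TRUE) else runif(n)
    y <- if (rep %% 4 == 0) sample(1:3, n, TRUE) else runif(n)
    p <- mine_params(B = B, c = 50)  # no coarsening at these sizes
    expect_equal(mic_e(x, y, p), oracle_mic(x, y, B), tolerance = 1e-12)
    expect_equal(tic_e(x, y, p), oracle_tic(x, y, B), tolerance = 1e-12)
  }
})

test_that("statistics are symmetric, rank-invariant and deterministic", {
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(40)
    y <- runif(40)
    p <- mine_params()
    expect_identical(mic_e(x, y, p), mic_e(y, x, p))
    expect_identical(tic_e(x, y, p), tic_e(y, x, p))
    # strictly increasing transforms leave the statistics bit-identical
    expect_identical(mic_e(exp(x), y^3 + 2 * y, p), mic_e(x, y, p))
    expect_identical(tic_e(qnorm(x), atan(y), p), tic_e(x, y, p))
    expect_identical(tic_e(x, y, p), tic_e(x, y, p))
  }
})

test_that("mic_e saturates on noiseless lines and decays for independence", {
  set.seed(3)
  x <- runif(100)
  expect_gte(mic_e(x, 3 * x + 7, mine_params(B = grid_bound(100, 0.75))), 0.99)
  m_small <- mean(replicate(5, mic_e(runif(100), runif(100),
                                     mine_params(B = grid_bound(100, 0.75)))))
  m_large <- mean(replicate(5, mic_e(runif(1000), runif(1000),
                                     mine_params(B = grid_bound(1000, 0.65)))))
  expect_lt(m_large, m_small)  # estimator bias shrinks with n
  expect_lt(m_large, 0.25)
})

test_that("tic_e is bounded by the number of characteristic entries", {
  set.seed(11)
  # n divisible by 2, 3 and 4: every grid shape saturates on a noiseless
  # monotone pair, so tic_e hits its bound |{(k,l): kl <= 9}| = 6 exactly
  x <- runif(48)
  expect_equal(tic_e(x, 2 * x - 1), 6, tolerance = 1e-12)
  expect_lte(tic_e(x, runif(48)), 6)
})
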