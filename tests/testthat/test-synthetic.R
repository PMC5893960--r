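test_that("the noise-intensity pool contains exactly the 18,000 stated values", {
  pool <- noise_pool()
  expect_length(pool, 18000)
  expect_equal(pool[1], 0.05)
  expect_equal(pool[18000], 8.998)
  expect_true(all(pool >= 0.05 & pool < 9))
  expect_false(is.unsorted(pool))
  # the three half-open segments have steps 1e-4, 2e-4, 2e-3
  expect_equal(sum(pool < 1), 9500)
  expect_equal(sum(pool >= 1 & pool < 2), 5000)
  expect_equal(sum(pool >= 2), 3500)
})

test_that("functional forms evaluate to their defining values", {
  expect_equal(eval_function("line", 0.5), 0.5)
  expect_equal(eval_function("exponential", 1), 2)
  expect_equal(eval_function("exponential", 0), 1)
  d <- seq(0.05, 0.45, by = 0.1)  # parabola is symmetric about 1/2
  expect_equal(eval_function("parabola", 0.5 - d),
               eval_function("parabola", 0.5 + d))
  expect_equal(eval_function("sigmoid", 0.5), 0.5)
  expect_equal(eval_function("spike", 0.05), 1)
  expect_equal(eval_function("spike", 1), 0)
  expect_equal(eval_function("cubic", c(0, 1)), c(-1, 1))  # odd about 1/2
  expect_error(eval_function("helix", 0.5), "unknown function")
})

test_that("sd_generate honours the design counts exactly", {
  d <- sd_generate(60000, 0.01, n_samples = 25, seed = 1)
  expect_equal(sum(d$truth$is_dependent), 600)
  expect_equal(sum(!d$truth$is_dependent), 59400)
  expect_identical(dim(d$x), c(60000L, 25L))
  # effect_chance = 1 makes every pair dependent
  d1 <- sd_generate(50, 1, 20, seed = 2)
  expect_true(all(d1$truth$is_dependent))
  expect_true(all(d1$truth$r2 >= 0 & d1$truth$r2 <= 1))
  # non-integral dependent count is rejected
  expect_error(sd_generate(1000, 0.0015, 20), "integer")
})

test_that("sd_generate is deterministic under seed and r2 spans (0, 1)", {
  a <- sd_generate(300, 0.1, 40, seed = 5)
  b <- sd_generate(300, 0.1, 40, seed = 5)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$truth, b$truth)
  # k_eta pool extremes push the realized signal share towards 0 and 1
  d <- sd_generate(200, 1, 1000, seed = 6)
  expect_lt(min(d$truth$r2), 0.05)
  expect_gt(max(d$truth$r2), 0.95)
  # near-zero noise forces r2 -> 1: check via the k_eta/r2 relation
  low <- d$truth$k_eta < 0.1
  if (any(low)) expect_true(all(d$truth$r2[low] > 0.9))
})

test_that("madelon_generate reproduces the 200-variable cluster design", {
  m <- madelon_generate(48, seed = 3)
  expect_identical(dim(m$data), c(200L, 48L))
  expect_equal(nrow(m$truth), 19900)          # (200 * 199) / 2 tested pairs
  expect_equal(sum(m$truth$is_dependent), 190)
  expect_equal(as.integer(table(m$clusters)), rep(12L, 4))
  expect_equal(sort(unique(m$classes)), c(0L, 1L))
  expect_equal(as.integer(table(m$classes)), c(24L, 24L))
  # redundant variables are exact linear combinations of the informative ones
  inf <- m$data[1:5, ]
  red <- m$data[6:20, ]
  expect_equal(unname(red), unname(m$coef %*% inf), tolerance = 1e-12)
  expect_equal(qr(rbind(inf, red))$rank, 5)
  # relation classes partition the dependent set
  expect_equal(as.integer(table(m$truth$relation)),
               c(10L, 75L, 19710L, 105L))  # II, IR, null, RR
  m2 <- madelon_generate(48, seed = 3)
  expect_identical(m$data, m2$data)
  expect_error(madelon_generate(6), ">= 8")
})

test_that("score_detection counts TP/FP/FN per the empty-call convention", {
  truth <- data.frame(pair_id = c("a", "b", "c", "d"),
                      is_dependent = c(TRUE, TRUE, FALSE, FALSE))
  res <- data.frame(pair_id = c("d", "c", "b", "a"),  # order-free matching
                    adjusted = c(0.01, 0.8, 0.02, 0.7))
  sc <- score_detection(res, truth, 0.05)
  expect_equal(sc$power, 0.5)      # b detected, a missed
  expect_equal(sc$fp_count, 1)     # d called, independent
  expect_equal(sc$fdr, 0.5)
  expect_equal(sc$fn_count, 1)
  # all detected, no FP
  res2 <- data.frame(pair_id = c("a", "b", "c", "d"),
                     adjusted = c(0.01, 0.01, 0.5, 0.5))
  sc2 <- score_detection(res2, truth, 0.05)
  expect_equal(sc2$power, 1)
  expect_equal(sc2$fdr, 0)
  # nothing detected: fdr 0 by convention, all dependents are FNs
  res3 <- transform(res2, adjusted = 0.9)
  sc3 <- score_detection(res3, truth, 0.05)
  expect_equal(sc3$power, 0)
  expect_equal(sc3$fdr, 0)
  expect_equal(sc3$fn_count, 2)
  expect_error(score_detection(res2[1:3, ], truth, 0.05), "identical pair ids")
})
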