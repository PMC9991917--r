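test_that("crossing splits follow the thirds arithmetic", {
  ev <- event_stream(c(0, 30, 40, 52), c("crossing_start", "crossing_end",
                                         "crossing_start", "crossing_end"))
  sp <- split_crossings(ev)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$t_a[1], 10)
  expect_equal(sp$t_b[1], 20)
  expect_equal(sp$t_a[2], 44)
  bad <- event_stream(c(5, 5), c("crossing_start", "crossing_end"))
  expect_error(split_crossings(bad), class = "neurowire_error_bad_events")
})

test_that("equalized means are exact for equal or constant conditions", {
  ev <- event_stream(c(0, 30), c("crossing_start", "crossing_end"))
  sp <- split_crossings(ev)
  fs <- 10
  bp <- matrix(rnorm(300 * 2), 300, 2, dimnames = list(NULL, c("a", "b")))
  m <- equalized_condition_means(bp, fs, sp, n_iter = 50, seed = 1)
  # equal-length conditions: subsampling is the identity
  ii <- neurowire:::interval_samples(sp$t_a, sp$t_b, fs, 300)
  bi <- neurowire:::interval_samples(sp$t_b, sp$t_end, fs, 300)
  expect_equal(m$inner_mean, unname(colMeans(bp[ii, ])))
  expect_equal(m$boundary_mean, unname(colMeans(bp[bi, ])))
  # constant series: both means equal the constant
  cbp <- matrix(7, 300, 2)
  mc <- equalized_condition_means(cbp, fs, sp, seed = 2)
  expect_equal(mc$inner_mean, c(7, 7))
  expect_equal(mc$boundary_mean, c(7, 7))
  # determinism under unequal conditions
  ev2 <- event_stream(c(0, 24), c("crossing_start", "crossing_end"))
  sp2 <- split_crossings(ev2)
  bp2 <- matrix(rnorm(400), 400, 1)
  m1 <- equalized_condition_means(bp2, fs, sp2, seed = 5)
  m2 <- equalized_condition_means(bp2, fs, sp2, seed = 5)
  expect_identical(m1, m2)
})

test_that("the sign-flip test matches exhaustive enumeration", {
  # n = 2, diffs [1, -1]: permuted means {1, 0, 0, -1}; |obs| = 0 -> p = 1
  pt <- paired_permutation_test(c(2, 1), c(1, 2), n_perm = 100)
  expect_true(pt$exact)
  expect_equal(pt$p_value, 1.0)
  expect_equal(pt$observed_diff, 0)
  # independent exhaustive oracle for random n = 8 data
  set.seed(13)
  a <- rnorm(8, 0.4)
  b <- rnorm(8)
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  oracle <- mean(abs(signs %*% d / 8) >= abs(mean(d)))
  exact <- paired_permutation_test(a, b, n_perm = 2^8)
  expect_true(exact$exact)
  expect_equal(exact$p_value, oracle)
  # Monte-Carlo mode approaches the same value
  mc <- paired_permutation_test(a, b, n_perm = 20000, seed = 3, exact = FALSE)
  expect_false(mc$exact)
  expect_lt(abs(mc$p_value - oracle), 0.02)
})

test_that("identical same-sign differences give the two-pattern p-value", {
  pt <- paired_permutation_test(rep(2, 16), rep(1, 16), n_perm = 2^16)
  expect_equal(pt$p_value, 2 / 2^16)
  # a == b gives p = 1
  x <- rnorm(8)
  expect_equal(paired_permutation_test(x, x, n_perm = 256)$p_value, 1.0)
})

test_that("p is invariant to common scaling of the bandpower values", {
  set.seed(4)
  a <- rnorm(10, 0.3)
  b <- rnorm(10)
  p1 <- paired_permutation_test(a, b, n_perm = 2^10)$p_value
  p2 <- paired_permutation_test(100 * a, 100 * b, n_perm = 2^10)$p_value
  expect_equal(p1, p2)
})

test_that("the smoothed estimator and one-sided options behave", {
  a <- c(3, 4, 5, 6)
  b <- c(1, 1, 1, 1)
  ps <- paired_permutation_test(a, b, n_perm = 16, smoothed = TRUE)
  expect_equal(ps$p_value, (2 + 1) / (16 + 1))
  pg <- paired_permutation_test(a, b, n_perm = 16, alternative = "greater")
  expect_equal(pg$p_value, 1 / 16)
})

test_that("a strong boundary effect is detected end to end", {
  ws <- gen_walk_session(boundary_gain = 2, n_channels = 8, seed = 44)
  res <- boundary_theta_test(ws$rec, ws$events, n_perm = 2000, seed = 9)
  expect_lt(res$test$p_value, 0.01)
  expect_gt(res$test$observed_diff, 0)
  expect_equal(nrow(res$means), 8)
})
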