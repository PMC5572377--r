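test_that("correlate returns the Pearson r and t-distribution p", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  ct <- correlate(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(ct$r, 0.8)
  # p from t = r sqrt(n-2) / sqrt(1-r^2) on n-2 df, by hand
  t_hand <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(ct$p, 2 * pt(-t_hand, df = 3), tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "degenerate")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("dependent-correlation z is zero at equal correlations and tracks their order", {
  for (rkh in c(0, 0.3, 0.7)) {
    res <- compare_dependent_correlations(0.4, 0.4, rkh, n = 24)
    expect_equal(res$z_stat, 0)
    expect_equal(res$p, 1)
  }
  up <- compare_dependent_correlations(0.6, 0.2, 0.3, n = 24)
  dn <- compare_dependent_correlations(0.2, 0.6, 0.3, n = 24)
  expect_gt(up$z_stat, 0)
  expect_equal(up$z_stat, -dn$z_stat, tolerance = 1e-12)
  expect_equal(sign(up$z_stat), sign(atanh(0.6) - atanh(0.2)))
})

test_that("dependent-correlation |z| grows with the cross-correlation of the compared variables", {
  # r_kh is swept over the values for which (-0.533, -0.106, r_kh) remains a
  # valid correlation triple; beyond ~0.85 the matrix loses positive
  # semidefiniteness and the test rejects it (checked below).
  zs <- vapply(seq(0, 0.8, by = 0.1), function(rkh) {
    abs(compare_dependent_correlations(-0.533, -0.106, rkh, n = 24)$z_stat)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(compare_dependent_correlations(-0.533, -0.106, 0.95, n = 24),
               "positive semidefinite")
})

test_that("dependent-correlation test rejects invalid correlation triples", {
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, n = 24), "\\|r\\| < 1")
  # r_jk = 0.9, r_jh = 0.9 but r_kh = -0.9 is not a valid correlation matrix
  expect_error(compare_dependent_correlations(0.9, 0.9, -0.9, n = 24),
               "positive semidefinite")
})

test_that("dependent-correlation test is calibrated under equal population correlations", {
  skip_if_not_installed("MASS")
  set.seed(1009)
  n <- 24; reps <- 2000
  Sigma <- matrix(c(1, 0.3, 0.3,
                    0.3, 1, 0.4,
                    0.3, 0.4, 1), 3, 3)
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    d <- MASS::mvrnorm(n, rep(0, 3), Sigma)
    r <- cor(d)
    rej[i] <- compare_dependent_correlations(r[1, 2], r[1, 3], r[2, 3], n)$p < 0.05
  }
  ci_half <- 2.5758 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), ci_half)
})

test_that("between-subject permutation p-values behave at the extremes and reproduce by seed", {
  set.seed(66)
  y <- rnorm(24)
  res <- permutation_test_between(y, y, n_perm = 200, seed = 4)
  expect_equal(res$r_obs, 1)
  expect_lte(res$p_one, 2 / 201)  # add-one rule; identity redraws only
  expect_identical(res$n_possible, factorial(24))
})

test_that("permutation tests are bit-reproducible given (seed, n_perm)", {
  set.seed(31)
  x <- rnorm(12); xc <- rnorm(12); y <- rnorm(12)
  a <- permutation_test_between(x, y, n_perm = 300, seed = 7)
  b <- permutation_test_between(x, y, n_perm = 300, seed = 7)
  expect_identical(a$null_dist, b$null_dist)
  c <- permutation_test_between(x, y, n_perm = 300, seed = 8)
  expect_false(identical(a$null_dist, c$null_dist))
  w1 <- permutation_test_within(x, xc, y, n_perm = 300, seed = 7)
  w2 <- permutation_test_within(x, xc, y, n_perm = 300, seed = 7)
  expect_identical(w1$null_dist, w2$null_dist)
})

test_that("within-subject swaps are no-ops when the conditions are identical", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10)
  res <- permutation_test_within(x, x, y, n_perm = 100, seed = 2)
  expect_equal(res$null_dist, rep(res$r_obs, 100), tolerance = 1e-12)
  expect_equal(res$p_one, 1)
  expect_equal(res$p_two, 1)
  expect_identical(res$n_possible, 2^10)
})

test_that("degenerate permutation inputs raise errors", {
  expect_error(permutation_test_between(rep(1, 8), rnorm(8)), "degenerate")
  expect_error(permutation_test_within(rep(1, 8), rnorm(8), rnorm(8)), "degenerate")
  expect_error(permutation_test_between(rnorm(4), rnorm(4)), "length")
})

test_that("LOOCV is exact on noiseless linear data and matches the hand oracle", {
  set.seed(3)
  x <- rnorm(12)
  res <- loocv_predict(x, 2 * x + 500)
  expect_true(all(abs(res$rel_error) < 1e-10))

  # 4-subject fixture, fold-1 regression worked by hand:
  # train x = (2,3,4), y = (12,14,17): slope 2.5, intercept 6.8333,
  # prediction at x = 1 is 9.3333, rel error -0.066667
  toy <- loocv_predict(c(1, 2, 3, 4), c(10, 12, 14, 17))
  expect_equal(toy$predicted[1], 9 + 1 / 3, tolerance = 1e-9)
  expect_equal(toy$rel_error[1], (9 + 1 / 3 - 10) / 10, tolerance = 1e-9)
  expect_equal(toy$max_abs_error, max(abs(toy$rel_error)))
})

test_that("LOOCV error shrinks with the noise level (monotone sweep)", {
  set.seed(18)
  x <- rnorm(24)
  base <- 900 - 80 * x
  errs <- vapply(c(60, 20, 0), function(sd) {
    set.seed(100 + sd)
    loocv_predict(x, base + rnorm(24, 0, sd))$max_abs_error
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("LOOCV rejects zero outcomes and degenerate folds", {
  expect_error(loocv_predict(1:5, c(1, 0, 3, 4, 5)), "zero")
  expect_error(loocv_predict(c(2, 1, 1, 1, 1), 1:5), "degenerate training fold")
})

test_that("paired t test matches hand computation and handles ties", {
  set.seed(5)
  z <- rnorm(8)
  same <- paired_t_test(z, z)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # differences (1, 2, 3): mean 2, sd 1, t = 2 sqrt(3), df 2
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)

  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})
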