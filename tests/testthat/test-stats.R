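test_that("the Welch statistic matches its closed form", {
  a <- c(0, 1, 2)
  b <- c(1, 2, 3)
  res <- two_sample_t(a, b)
  # equal n and equal variance: t = (mean(a)-mean(b)) / sqrt(2 * s^2 / n)
  expect_equal(res$t, (1 - 2) / sqrt(2 * 1 / 3), tolerance = 1e-12)
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-12)

  # general closed form with unequal variances (Welch-Satterthwaite)
  set.seed(31)
  x <- rnorm(20, 0, 1)
  y <- rnorm(35, 0.5, 2)
  res <- two_sample_t(x, y)
  se2 <- var(x) / 20 + var(y) / 35
  expect_equal(res$t, (mean(x) - mean(y)) / sqrt(se2), tolerance = 1e-12)
  expect_equal(
    res$df,
    se2^2 / ((var(x) / 20)^2 / 19 + (var(y) / 35)^2 / 34),
    tolerance = 1e-12
  )
  expect_equal(res$p_uncorrected, 2 * pt(-abs(res$t), res$df), tolerance = 1e-12)
})

test_that("identical and degenerate samples are handled", {
  a <- c(1, 2, 3, 4)
  res <- two_sample_t(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p_uncorrected, 1)

  res <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p_uncorrected, 1)

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("BH correction follows the step-up formula and is monotone", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_fdr, rep(0.04, 4))
  expect_true(all(out$significant))

  expect_equal(fdr_correct(0.03)$p_fdr, 0.03)

  p <- c(0.001, 0.008, 0.039, 0.041, 0.3)
  out <- fdr_correct(p)
  # step-up: p_(i) * m / i, cumulative minimum from the largest
  manual <- rev(cummin(rev(sort(p) * 5 / seq_len(5))))[rank(p)]
  expect_equal(out$p_fdr, manual)
  expect_true(all(out$p_fdr >= p))

  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(fdr_correct(p[perm])$p_fdr, out$p_fdr[perm])

  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the test's type-I error rate is nominal under the null", {
  set.seed(77)
  reps <- 2000
  rejections <- 0
  for (i in seq_len(reps)) {
    x <- rnorm(30)
    y <- rnorm(30)
    if (two_sample_t(x, y)$p_uncorrected < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("condition comparison reports four scopes with joint FDR", {
  set.seed(55)
  rr <- lapply(c(32, 64, 64), function(m) matrix(rexp(20 * m, 10), 20, m))
  fr <- lapply(rr, function(m) m + 0.05) # uniformly higher activations
  out <- compare_conditions(rr, fr)
  expect_equal(nrow(out), 4L)
  expect_equal(out$scope, c("1", "2", "3", "all"))
  expect_true(all(out$t > 0)) # FR first, FR larger
  expect_true(all(out$mean_fr > out$mean_rr))
  expect_true(all(out$p_fdr >= out$p_uncorrected))
  expect_equal(out$n_fr, c(20 * 32, 20 * 64, 20 * 64, 20 * 160))

  # per-image sensitivity mode: one value per image, same mean contrast
  per_img <- compare_conditions(rr, fr, unit = "image")
  expect_equal(per_img$n_fr, rep(20L, 4))
  expect_equal(per_img$mean_fr - per_img$mean_rr, rep(0.05, 4), tolerance = 1e-12)

  # identical inputs: no contrast anywhere
  same <- compare_conditions(rr, rr)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_fdr == 1))
  expect_false(any(same$significant))
})
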