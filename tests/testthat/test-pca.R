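# Brute-force oracle: explicitly form the covariance (or correlation) matrix
# and eigendecompose it.
brute_spectrum <- function(x, type = "covariance") {
  m <- if (type == "covariance") cov(x) else cor(x[, apply(x, 2, var) > 0, drop = FALSE])
  sort(pmax(eigen(m, symmetric = TRUE, only.values = TRUE)$values, 0),
    decreasing = TRUE
  )
}

test_that("the PCA spectrum matches brute-force covariance eigendecomposition", {
  set.seed(101)
  cases <- list(
    matrix(rnorm(20), 5, 4),
    matrix(rnorm(200 * 50), 200, 50),
    matrix(rexp(60 * 10), 60, 10),
    # wide matrix exercises the SVD path (n - 1 non-null components)
    matrix(rnorm(40 * 600), 40, 600)
  )
  for (x in cases) {
    res <- run_pca(x)
    ref <- brute_spectrum(x)
    k <- length(res$eigenvalues)
    expect_equal(res$eigenvalues, ref[seq_len(k)], tolerance = 1e-8)
    expect_equal(res$ev_ratio, (ref / sum(ref))[seq_len(k)], tolerance = 1e-8)
    # ratios are non-negative, descending, and sum to at most 1
    expect_true(all(diff(res$eigenvalues) <= 1e-12))
    expect_lte(sum(res$ev_ratio), 1 + 1e-9)
    expect_true(all(diff(res$cumulative) >= -1e-12))
  }
})

test_that("correlation-mode PCA standardises and drops constant features", {
  set.seed(102)
  x <- cbind(matrix(rnorm(300), 100, 3) %*% matrix(rnorm(9), 3, 3), 5)
  res <- run_pca(x, pca_config("correlation"))
  expect_equal(res$n_features, 3L)
  ref <- brute_spectrum(x, "correlation")
  expect_equal(res$eigenvalues, ref, tolerance = 1e-8)
  expect_equal(res$total_variance, 3)
})

test_that("degenerate and structured inputs behave as documented", {
  # collinear 2-feature points: all variance on one component
  t <- seq(0, 1, length.out = 50)
  line <- cbind(2 * t + 1, -3 * t)
  res <- run_pca(line)
  expect_equal(res$ev_ratio, c(1, 0), tolerance = 1e-12)

  expect_error(run_pca(matrix(1, 10, 4)), "constant")
  expect_error(run_pca(matrix(rnorm(4), 2, 2)), "at least 3")

  # isotropic noise: each of 3 components explains about a third
  set.seed(103)
  iso <- matrix(rnorm(3e5), 1e5, 3)
  expect_true(all(abs(run_pca(iso)$ev_ratio - 1 / 3) < 0.02))
})

test_that("spectra are invariant to feature permutation", {
  set.seed(104)
  x <- matrix(rnorm(80 * 12), 80, 12)
  res1 <- run_pca(x)
  res2 <- run_pca(x[, sample.int(12)])
  expect_equal(res1$eigenvalues, res2$eigenvalues, tolerance = 1e-8)
})

fake_pca <- function(eigenvalues, total = sum(eigenvalues)) {
  ev <- eigenvalues / total
  structure(
    list(
      eigenvalues = eigenvalues, ev_ratio = ev, cumulative = cumsum(ev),
      n_samples = NA, n_features = length(eigenvalues),
      total_variance = total, matrix_type = "covariance"
    ),
    class = "psm_pca"
  )
}

test_that("weight of primary dimensions is the first two components' share", {
  expect_equal(wpd(fake_pca(c(0.6, 0.3, 0.1), total = 1)), 90)
  expect_equal(wpd(fake_pca(c(3, 0))), 100)
  expect_equal(wpd(fake_pca(rep(1, 100))), 2)
  expect_error(wpd(fake_pca(5)), "at least 2")
})

test_that("weight of secondary dimensions applies the strict eigenvalue threshold", {
  s <- wsd(fake_pca(c(4, 3, 2, 1.5, 0.5)))
  expect_equal(s$wsd, 100 * 3.5 / 11)
  expect_equal(s$n_secondary, 2L)

  s <- wsd(fake_pca(c(3, 2, 0.9, 0.8)))
  expect_equal(s$wsd, 0)
  expect_equal(s$n_secondary, 0L)

  # eigenvalues exactly 1 are excluded (strict inequality)
  s <- wsd(fake_pca(rep(1, 6)))
  expect_equal(s$wsd, 0)
  expect_equal(s$n_secondary, 0L)

  # a large first two do not leak into the secondary set
  s <- wsd(fake_pca(c(10, 5, 2, 1, 0.5)))
  expect_equal(s$n_secondary, 1L)
  expect_equal(s$wsd, 100 * 2 / 18.5)
})

test_that("d90 returns the minimal component count reaching 90%", {
  expect_equal(d90(fake_pca(c(0.8, 0.15, 0.05), total = 1)), 2L)
  expect_equal(d90(fake_pca(1)), 1L)
  expect_equal(d90(fake_pca(rep(0.01, 100), total = 1)), 90L)
  expect_error(d90(fake_pca(rep(0.2, 3), total = 1)), "max_components")
})

test_that("d90 minimality holds on every computed spectrum", {
  set.seed(105)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    p <- sample(3:30, 1)
    x <- matrix(rnorm(n * p), n, p) %*% diag(runif(p, 0.1, 3))
    res <- run_pca(x)
    m <- d90(res)
    expect_gte(res$cumulative[m], 0.9)
    if (m > 1) expect_lt(res$cumulative[m - 1], 0.9)
  }
})

test_that("identical networks produce identical dimensionality tables", {
  fx <- tiny_trained()
  tab <- dimensionality_table(fx$net, fx$net, fx$test,
    level = "filter",
    config = pca_config(max_components = 20L)
  )
  rr <- tab[tab$condition == "RR", c("wpd", "d90")]
  fr <- tab[tab$condition == "FR", c("wpd", "d90")]
  expect_equal(rr$wpd, fr$wpd)
  expect_equal(rr$d90, fr$d90)
  expect_equal(tab$scope[1:4], c("1", "2", "3", "all"))
  expect_true(all(is.na(tab$wsd))) # omitted at filter level
})
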