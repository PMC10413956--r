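# Group-comparison statistics, checked against brute-force oracles and
# the base-R reference implementations.

test_that("Mann-Whitney U matches hand values and is symmetric", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U1, 0)
  expect_equal(r$U2, 4)

  same <- suppressWarnings(mann_whitney_u(1:6, 1:6))
  expect_equal(same$U1, 18) # n^2 / 2
  expect_equal(same$U1, same$U2)

  x <- rnorm(15); y <- rnorm(20)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U1, b$U2)
  expect_equal(a$p, b$p)

  expect_warning(mann_whitney_u(rep(2, 5), rep(2, 7)), "tied")
})

test_that("U equals the O(n^2) pairwise-count oracle and the base-R
           statistic on random samples", {
  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    x <- sample(round(rnorm(n1, sd = 2), 1)) # coarse values induce ties
    y <- sample(round(rnorm(n2, sd = 2), 1))
    r <- mann_whitney_u(x, y)
    oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_identical(r$U1, oracle)
    expect_equal(r$U1 + r$U2, n1 * n2)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(r$U1, unname(ref$statistic))
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("KS D matches corners, the pooled-ECDF oracle, and base R", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)

  set.seed(22)
  for (i in 1:200) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.3)
    r <- ks_two_sample(x, y)
    grid <- sort(c(x, y)) # oracle: ECDF difference on the pooled support
    oracle <- max(abs(vapply(grid, function(g)
      mean(x <= g) - mean(y <= g), numeric(1))))
    expect_equal(r$D, oracle, tolerance = 1e-14)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(r$D, unname(ref$statistic), tolerance = 1e-14)
    # base R evaluates the same asymptotic distribution with its own
    # series cutoffs; agreement to ~1e-4 is the comparable scale
    expect_equal(r$p, ref$p.value, tolerance = 1e-3)
  }
})

test_that("KS is invariant under joint monotone transforms", {
  set.seed(23)
  x <- rlnorm(40); y <- rlnorm(30, 0.5)
  expect_equal(ks_two_sample(x, y)$D, ks_two_sample(log(x), log(y))$D)
  expect_equal(ks_two_sample(x, y)$D,
               ks_two_sample(sqrt(x), sqrt(y))$D)
})

test_that("chi-square matches the closed form, base R, and permutation
           invariance", {
  flat <- chi_square_rxc(matrix(10, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  m <- matrix(c(20, 10, 10, 20), 2)
  r <- chi_square_rxc(m)
  expect_equal(r$chi2, 100 / 15, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_true(all(r$expected == 15))
  ref <- stats::chisq.test(m, correct = FALSE)
  expect_equal(r$chi2, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)

  set.seed(24)
  big <- matrix(rpois(14, 20) + 1, nrow = 2) # 2 x 7
  rb <- chi_square_rxc(big)
  expect_equal(rb$df, 6L)
  perm <- big[, sample(7)]
  expect_equal(chi_square_rxc(perm)$chi2, rb$chi2)
  expect_equal(chi_square_rxc(big[2:1, ])$chi2, rb$chi2)

  expect_error(chi_square_rxc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_warning(chi_square_rxc(matrix(c(2, 3, 4, 1), 2)), "below 5")
})

test_that("two-proportion z matches its corners and the chi-square
           identity", {
  eq <- two_proportion_z(10, 40, 5, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  r <- two_proportion_z(44, 100, 75, 100)
  expect_gt(abs(r$z), 4)
  expect_lt(r$p, 0.001)
  expect_equal(sign(r$z), sign(r$p1_hat - r$p2_hat))

  # z^2 equals the 2x2 chi-square without continuity correction
  tab <- matrix(c(44, 56, 75, 25), 2, byrow = TRUE)
  expect_equal(r$z^2, chi_square_rxc(tab)$chi2, tolerance = 1e-12)

  expect_warning(two_proportion_z(0, 10, 0, 12), "degenerate")
})

test_that("Pearson r matches the covariance oracle and base R", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)

  set.seed(25)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    r <- pearson_correlation(x, y)
    oracle <- cov(x, y) / (sd(x) * sd(y))
    expect_equal(r$r, oracle, tolerance = 1e-12)
    ref <- stats::cor.test(x, y)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("null p-values are approximately uniform for the smooth
           tests", {
  set.seed(26)
  p_mw <- replicate(2000, mann_whitney_u(rnorm(60), rnorm(60))$p)
  expect_lt(suppressWarnings(
    stats::ks.test(p_mw, "punif")$statistic), 0.05)
  p_cor <- replicate(2000, pearson_correlation(rnorm(25), rnorm(25))$p)
  expect_lt(suppressWarnings(
    stats::ks.test(p_cor, "punif")$statistic), 0.05)
})
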