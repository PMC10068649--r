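test_that("Spearman correlation handles monotone and degenerate inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  ## invariance under strictly monotone transforms
  y <- c(2, 7, 1, 8, 2.8, 1.8, 3)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, y^3)$rho, base$rho)
  ## zero variance flagged as undefined
  z <- spearman_cor(rep(2, 6), y[1:6])
  expect_true(z$undefined)
  expect_true(is.na(z$rho))
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("Spearman with ties matches the rank-then-Pearson oracle", {
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  y <- c(2, 1, 3, 3, 5, 4, 6, 5, 7, 7)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  ## p-value via the documented t-approximation
  t_stat <- got$rho * sqrt((10 - 2) / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(-abs(t_stat), 8), tolerance = 1e-12)
  ## permutation option agrees in order of magnitude on small samples
  set.seed(53)
  perm <- spearman_cor(x, y, method = "permutation", n_perm = 4000)
  expect_lt(abs(perm$p - got$p), 0.05)
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(59)
  x <- rnorm(40); y <- rnorm(40)
  plain <- spearman_cor(x, y)
  expect_identical(partial_spearman(x, y, NULL), plain)
  const <- partial_spearman(x, y, rep(3, 40))
  expect_equal(const$rho, plain$rho, tolerance = 1e-12)
  expect_equal(const$p, plain$p, tolerance = 1e-12)
})

test_that("residual and inverse-matrix partial correlations agree", {
  set.seed(61)
  for (i in 1:10) {
    n <- 30
    Z <- cbind(rnorm(n), runif(n))
    x <- Z[, 1] + rnorm(n)
    y <- 0.5 * Z[, 1] - Z[, 2] + rnorm(n)
    got <- partial_spearman(x, y, Z)
    expect_equal(got$rho, oracle_partial_spearman(x, y, Z),
                 tolerance = 1e-10)
  }
})

test_that("controlling the common cause removes a spurious correlation", {
  set.seed(67)
  n <- 500
  z <- rnorm(n)
  y <- z + rnorm(n, 0, 0.2)   # outcome driven by z
  x <- rnorm(n)               # independent of both
  expect_lt(abs(partial_spearman(x, y, z)$rho), 0.1)
  ## and a real partial association survives
  x2 <- z + rnorm(n, 0, 0.5)
  y2 <- z + x2 + rnorm(n, 0, 0.5)
  expect_gt(partial_spearman(x2, y2, z)$rho, 0.3)
})

test_that("collinear covariates are refused", {
  set.seed(71)
  z <- rnorm(30)
  expect_error(partial_spearman(rnorm(30), rnorm(30), cbind(z, 2 * z)),
               "collinear")
  expect_error(partial_spearman(rnorm(8), rnorm(8),
                                matrix(rnorm(8 * 5), 8, 5)),
               "covariates \\+ 3")
})

test_that("chi-squared independence matches its oracle and conventions", {
  balanced <- chi2_independence(rep(c("a", "b"), each = 50),
                                rep(rep(c("x", "y"), each = 25), 2))
  expect_equal(balanced$chi2, 0)
  expect_equal(balanced$p, 1)
  perfect <- chi2_independence(rep(c(1, 2), each = 20),
                               rep(c("u", "v"), each = 20))
  expect_equal(perfect$chi2, 40)
  expect_equal(perfect$df, 1)
  ## 2x4 fixture against the brute-force O/E oracle
  a <- rep(c("p", "q"), c(12, 18))
  b <- c(rep(1:4, c(2, 4, 3, 3)), rep(1:4, c(6, 2, 5, 5)))
  got <- chi2_independence(a, b)
  expect_equal(got$chi2, oracle_chi2(unclass(table(a, b))),
               tolerance = 1e-12)
  expect_equal(got$df, 3)
  ## symmetry in the two arguments
  swapped <- chi2_independence(b, a)
  expect_equal(swapped$chi2, got$chi2, tolerance = 1e-12)
  expect_equal(swapped$p, got$p, tolerance = 1e-12)
  ## empty categories dropped with a warning before df
  f <- factor(rep(c("a", "b"), 10), levels = c("a", "b", "c"))
  expect_warning(res <- chi2_independence(f, rep(1:2, each = 10)),
                 "empty")
  expect_equal(res$df, 1)
  expect_error(chi2_independence(rep("a", 10), rep(1:2, 5)),
               "2 categories")
})

test_that("p-values are uniform under permutation of one input", {
  set.seed(73)
  x <- rnorm(30); y <- rnorm(30)
  ps <- replicate(500, spearman_cor(x, sample(y))$p)
  expect_true(all(ps >= 0 & ps <= 1))
  d <- oracle_ks_stat(ps, runif(5000))
  expect_lt(d, 0.1)
})

test_that("the subgroup linear model recovers exact and noisy signals", {
  koos <- rep(1:4, each = 25)
  n_g <- c(18, 57, 70, 55)[koos]
  exact <- 2 * koos + 0.1 * n_g + 1
  fit <- suppressWarnings(glm_subgroup(exact, koos, n_g))
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(1, 2, 0.1),
               tolerance = 1e-9)
  ## constant response: slopes zero, F flagged undefined
  const <- suppressWarnings(glm_subgroup(rep(5, 100), koos, n_g))
  expect_true(const$constant_response)
  expect_true(is.na(const$f_statistic))
  expect_equal(unname(const$coefficients[2:3, "Estimate"]), c(0, 0),
               tolerance = 1e-12)
  expect_error(glm_subgroup(rnorm(10), rep(2, 10), rep(50, 10)),
               "2 Koos levels")
  ## collinear design named in the error
  expect_error(glm_subgroup(rnorm(8), rep(1:2, 4), rep(1:2, 4) * 10),
               "collinear")
})
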