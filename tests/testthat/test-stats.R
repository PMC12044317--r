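test_that("pearsonCI recovers exact and degenerate correlations", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearsonCI(x, x * 2 + 1)$r, 1)
  expect_equal(pearsonCI(x, -x)$r, -1)
  expect_error(pearsonCI(rep(1, 10), rnorm(10)), "x is degenerate")
  expect_error(pearsonCI(rnorm(10), rep(2, 10)), "y is degenerate")
  expect_error(pearsonCI(1:3, 3:1), "n >= 4")

  set.seed(4)
  x <- rnorm(200); y <- 0.3 * x + rnorm(200)
  res <- pearsonCI(x, y)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  expect_equal(res$p, cor.test(x, y)$p.value)
})

test_that("the Fisher-z interval reproduces the published index bounds", {
  ci <- fisherCI(0.14, 637)
  expect_lt(abs(ci[1] - 0.062), 0.002)
  expect_lt(abs(ci[2] - 0.214), 0.002)
})

test_that("Fisher-z intervals achieve nominal coverage", {
  # 2000 bivariate-normal replicates at the study's rho and n
  set.seed(5)
  rho <- 0.14; n <- 637
  hits <- vapply(1:2000, function(b) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- fisherCI(cor(x, y), n)
    ci[1] <= rho && rho <= ci[2]
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("average variance extracted matches its closed forms", {
  x <- c(2, 4, 9, 1)
  expect_equal(avgVarianceExtracted(x, x)$ave, 1)
  res <- avgVarianceExtracted(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$cov, 2)
  expect_equal(res$ave, 0.8)
  expect_false(res$below_threshold)
  expect_true(avgVarianceExtracted(rnorm(20), rnorm(20))$below_threshold)
  expect_error(avgVarianceExtracted(rep(1, 5), rep(3, 5)), "degenerate")

  # population value 0 for independent variables
  set.seed(6)
  expect_lt(abs(avgVarianceExtracted(rnorm(1e5), rnorm(1e5))$ave), 0.02)

  # invariant to a common positive rescaling
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(avgVarianceExtracted(3.7 * a, 3.7 * b)$ave,
               avgVarianceExtracted(a, b)$ave)
})

test_that("correlation LRT vanishes at the unconstrained optimum", {
  set.seed(7)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  r <- cor(x, y)
  expect_equal(lrtCorrelation(x, y, r)$chi2, 0, tolerance = 1e-8)
  # nonnegative everywhere
  for (rho0 in seq(-0.95, 0.95, by = 0.19))
    expect_gte(lrtCorrelation(x, y, rho0)$chi2, 0)
  # exactly collinear data are consistent with the capped boundary null
  res <- lrtCorrelation(x, 2 * x + 3, 1)
  expect_true(res$capped)
  expect_lt(res$chi2, 1e-6)
})

test_that("LRT rejects perfect correlation for weakly correlated data", {
  set.seed(8)
  n <- 637; rho <- 0.14
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(lrtCorrelation(x, y, 1)$p, 0.001)
})

test_that("cubic fit uses an orthonormal basis with mean intercept", {
  set.seed(9)
  nprs <- sample(0:10, 300, replace = TRUE)
  # constant response
  res0 <- cubicLogFit(rep(exp(3) - 1, 300), nprs)
  expect_equal(unname(res0$coefficients["intercept"]), 3)
  expect_equal(unname(res0$coefficients[2:4]), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(res0$r2, 0)

  # intercept equals the mean log response, always
  surface <- rexp(300, 1 / 500)
  res <- cubicLogFit(surface, nprs)
  expect_equal(unname(res$coefficients["intercept"]),
               mean(log(surface + 1)))

  # an exactly cubic response is fitted perfectly; cross-check the fitted
  # values against a raw-power least-squares oracle
  y <- 2 + 0.5 * nprs - 0.07 * nprs^2 + 0.004 * nprs^3
  resc <- cubicLogFit(exp(y) - 1, nprs)
  expect_equal(resc$r2, 1, tolerance = 1e-9)
  X <- cbind(1, nprs, nprs^2, nprs^3)
  beta <- qr.solve(X, y)
  expect_equal(unname(fitted(resc$fit)), unname(as.vector(X %*% beta)),
               tolerance = 1e-8)
  expect_error(cubicLogFit(1:4, c(1, 2, 3, 4)), "n > 5")
})

test_that("loess curves are exact on lines and match a WLS oracle", {
  set.seed(10)
  x <- sort(runif(50, 0, 10))
  yl <- 2 + 3 * x
  cv <- loessCurve(x, yl, span = 0.75, grid = seq(1, 9, length.out = 7))
  expect_equal(cv$fitted, 2 + 3 * cv$x, tolerance = 1e-6)

  # symmetric parabola data give a symmetric curve
  xs <- seq(-5, 5, length.out = 41)
  cvp <- loessCurve(xs, xs^2, span = 0.6, grid = seq(-4, 4, length.out = 9))
  expect_equal(cvp$fitted, rev(cvp$fitted), tolerance = 1e-8)

  # independent tricube local-linear oracle at 5 grid points
  y <- sin(x) + rnorm(50, 0, 0.1)
  span <- 0.75
  grid <- seq(1, 9, length.out = 5)
  got <- loessCurve(x, y, span = span, grid = grid)$fitted
  q <- floor(length(x) * span)
  oracle <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- pmax(0, 1 - (d / dq)^3)^3
    stats::lm.wfit(cbind(1, x - x0), y, w)$coefficients[1]
  }, 0)
  expect_equal(got, unname(oracle), tolerance = 1e-8)
  expect_error(loessCurve(x, y, span = 1.5), "span")
  expect_error(loessCurve(x, y, span = 0), "span")
})

test_that("Jonckheere-Terpstra reduces to Mann-Whitney for two groups", {
  set.seed(11)
  for (rep in 1:10) {
    g1 <- sample(0:10, 8, replace = TRUE)
    g2 <- sample(0:10, 6, replace = TRUE)
    jt <- jonckheereTest(list(g1, g2))$jt
    expect_equal(jt, mannWhitneyU(g1, g2))
  }
})

test_that("fully concordant groups reach the maximal statistic", {
  res <- jonckheereTest(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$jt, 12)   # all 12 cross-pairs concordant
  # decreasing alternative on reversed data gives the same statistic
  res2 <- jonckheereTest(list(c(5, 6), c(3, 4), c(1, 2)),
                         alternative = "decreasing")
  expect_equal(res2$jt, 12)
  expect_equal(res2$p, res$p)
  expect_error(jonckheereTest(list(1:3)), "at least 2 groups")
})

test_that("normal approximation agrees with the exact permutation law", {
  # tiny instances: full enumeration
  set.seed(12)
  for (rep in 1:5) {
    groups <- list(sample(0:5, 3, TRUE), sample(0:5, 3, TRUE),
                   sample(0:5, 3, TRUE))
    pn <- jonckheereTest(groups, method = "normal")$p
    pe <- jonckheereTest(groups, method = "permutation")$p
    expect_lt(abs(pn - pe), 0.06)   # coarse law at N = 9
  }
  # moderate instances: Monte-Carlo permutation
  set.seed(13)
  for (rep in 1:10) {
    groups <- lapply(1:4, function(g) sample(0:10, 8, TRUE) + g * 0.3)
    pn <- jonckheereTest(groups, method = "normal")$p
    pp <- jonckheereTest(groups, method = "permutation", nperm = 4000)$p
    expect_lt(abs(pn - pp), 0.02)
  }
})

test_that("the published stratum structure yields a decisive trend", {
  set.seed(14)
  means <- c(5.1, 5.4, 6.4, 7.2); sds <- c(2.7, 1.9, 1.8, 1.8)
  ns <- c(31, 154, 207, 242)
  groups <- lapply(1:4, function(g)
    pmin(10, pmax(0, round(rnorm(ns[g], means[g], sds[g])))))
  expect_lt(jonckheereTest(groups, alternative = "increasing")$p, 0.001)
})

test_that("color usage rates summarise the count distribution", {
  expect_equal(colorUsageRates(rep(1L, 20))$multi_rate, 0)
  expect_equal(colorUsageRates(rep(0:4, 10))$multi_rate, 0.6)
  counts <- rep(0:4, times = c(3, 210, 218, 155, 51))
  res <- colorUsageRates(counts)
  expect_equal(res$multi_rate, 424 / 637)
  expect_equal(round(100 * res$multi_rate, 1), 66.6)
  expect_error(colorUsageRates(integer(0)), "empty")
})

test_that("variance explained equals squared Pearson correlation", {
  x <- seq(0, 10, length.out = 30)
  res <- varianceExplained(x, x, nBoot = 200)
  expect_equal(res$r2, 1)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))

  set.seed(15)
  a <- rnorm(100); b <- 0.4 * a + rnorm(100)
  expect_equal(varianceExplained(a, b, nBoot = 50)$r2, pearsonCI(a, b)$r^2)
  # independent data: R^2 near zero with CI lower bound at ~0
  u <- rnorm(637); v <- rnorm(637)
  res2 <- varianceExplained(u, v, nBoot = 400)
  expect_lt(res2$r2, 0.02)
  expect_lt(res2$ci_low, 0.01)
})
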