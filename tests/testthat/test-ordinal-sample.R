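test_that("covariates are z-scored with the n-denominator convention", {
  d <- data.frame(g = c(0, 1, 1, 2), y = c(1, 2, 1, 3),
                  z = c(1, -1, 2, -2))
  s <- ordinal_sample(d)
  expect_equal(unname(colMeans(s$Z)), 0, tolerance = 1e-10)
  expect_equal(mean(s$Z[, 1]^2), 1, tolerance = 1e-10)
  expect_identical(s$g, c(0L, 1L, 1L, 2L))
  expect_identical(s$y, c(1L, 2L, 1L, 3L))
  # 2-level (dominant-style) genotype is a valid coding
  d2 <- data.frame(g = c(0, 1, 0, 1), y = c(1, 2, 2, 1), z = rnorm(4))
  expect_identical(length(ordinal_sample(d2)$g_levels), 2L)
})

test_that("degenerate and malformed inputs are rejected with diagnostics", {
  z <- rnorm(6)
  expect_error(ordinal_sample(data.frame(g = rep(0, 6), y = rep(1:2, 3),
                                         z = z)),
               "degenerate category structure")
  expect_error(ordinal_sample(data.frame(g = rep(0:1, 3), y = rep(1:2, 3),
                                         z = rep(2, 6))),
               "constant covariate")
  d <- data.frame(g = rep(0:1, 3), y = rep(1:2, 3), z = z)
  d$z[4] <- NA
  expect_error(ordinal_sample(d), "rows: 4")
  expect_error(ordinal_sample(d, genotype = "nope"), "not found")
})

test_that("thresholds are normal quantiles of cumulative proportions", {
  expect_equal(estimate_thresholds(c(150, 150)), 0)
  # the study's phenotype marginal
  eta <- estimate_thresholds(c(700, 100, 80, 70, 50))
  expect_equal(eta, qnorm(c(0.7, 0.8, 0.88, 0.95)), tolerance = 1e-12)
  expect_equal(eta, c(0.5244005, 0.8416212, 1.1749868, 1.6448536),
               tolerance = 1e-6)
  # round-trip: interval probabilities reproduce proportions exactly
  counts <- c(12, 40, 9, 30)
  cuts <- estimate_thresholds(counts)
  expect_equal(diff(c(0, pnorm(cuts), 1)), counts / sum(counts),
               tolerance = 1e-14)
  expect_error(estimate_thresholds(c(10, 0, 5)), "empty category")
})

test_that("covariate covariance is the n-denominator MLE and unit-diagonal", {
  set.seed(45)
  d <- data.frame(g = rep(0:1, 50), y = rep(1:2, 50), z1 = rnorm(100),
                  z2 = rnorm(100))
  s <- ordinal_sample(d)
  cv <- estimate_cov22(s$Z)
  expect_equal(unname(diag(cv$delta22)), c(1, 1), tolerance = 1e-10)
  expect_equal(cv$delta22 %*% cv$inverse, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(estimate_cov22(cbind(s$Z[, 1], s$Z[, 1])),
               "collinear")
})

test_that("independent covariates have vanishing sample correlation", {
  set.seed(46)
  Z <- matrix(rnorm(2e5), ncol = 2)
  Z <- scale(Z) # close enough to the package standardization for this check
  cv <- estimate_cov22(Z)
  expect_lt(abs(cv$delta22[1, 2]), 0.02)
})
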