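cov1 <- function(n = 50) {
  # unit 1x1 covariate covariance for single-covariate checks
  estimate_cov22(matrix(scale(rnorm(n)) * sqrt(n / (n - 1)), ncol = 1))
}

test_that("genotype-phenotype cell log-likelihood matches closed forms", {
  # independence: product of marginal interval probabilities
  xi <- c(-0.3, 0.8)
  eta <- c(-1, 0, 1)
  for (g in 0:2) {
    for (y in 1:4) {
      pg <- diff(pnorm(c(-Inf, xi, Inf)))[g + 1]
      py <- diff(pnorm(c(-Inf, eta, Inf)))[y]
      expect_equal(loglik_gy(g, y, xi, eta, 0), log(pg * py),
                   tolerance = 1e-12)
    }
  }
  # orthant cell at rho = 0.5
  expect_equal(loglik_gy(0L, 1L, 0, 0, 0.5), log(1 / 3), tolerance = 1e-10)
})

test_that("cell probabilities form a partition of unity", {
  xi <- c(-0.52, 0.91)
  eta <- qnorm(c(0.7, 0.8, 0.88, 0.95))
  tot <- 0
  for (g in 0:2) for (y in 1:5) {
    tot <- tot + exp(loglik_gy(g, y, xi, eta, 0.3))
  }
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("the pairwise likelihood is symmetric in the two ordinal margins", {
  xi <- c(-0.2)
  eta <- c(-0.9, 0.4)
  for (g in 0:1) for (y in 1:3) {
    expect_equal(loglik_gy(g, y, xi, eta, 0.37),
                 loglik_gy(y - 1L, g + 1L, eta, xi, 0.37),
                 tolerance = 1e-12)
  }
})

test_that("conditional genotype likelihood evaluates the plug-in normal", {
  cv <- cov1()
  xi <- 0
  # zeta = 0: marginal interval probability, independent of z
  expect_equal(loglik_gz(0L, matrix(2.7), xi, 0, cv), log(pnorm(0)),
               tolerance = 1e-12)
  # direct evaluation of the conditional mean/variance plug-in
  expect_equal(loglik_gz(0L, matrix(1), xi, 0.5, cv),
               log(pnorm((0 - 0.5) / sqrt(0.75))), tolerance = 1e-12)
  # partition of unity over genotype levels given z
  tot <- sum(exp(vapply(0:1, function(g)
    loglik_gz(g, matrix(-0.4), xi, 0.6, cv), numeric(1))))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("conditional phenotype likelihood mirrors the genotype block", {
  cv <- cov1()
  eta <- 0
  expect_equal(loglik_yz(2L, matrix(-1), eta, 0.6, cv),
               log(1 - pnorm((0 + 0.6) / sqrt(0.64))), tolerance = 1e-12)
  tot <- sum(exp(vapply(1:2, function(y)
    loglik_yz(y, matrix(0.9), eta, -0.3, cv), numeric(1))))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("infeasible dependence parameters and dead cells raise errors", {
  cv <- cov1()
  expect_error(loglik_gz(0L, matrix(1), 0, 1.2, cv),
               "invalid dependence parameters")
  expect_error(dependence_params(0.2, 1.1, 0.2, cv),
               "invalid dependence parameters")
  expect_error(dependence_params(1.5), "delta12")
  expect_error(loglik_gy(0L, 2L, -37, 37, 0), "zero-probability cell")
})
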