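unit_cov <- function() {
  z <- rnorm(40)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  estimate_cov22(matrix(z, ncol = 1))
}

test_that("rho and its gradient evaluate exactly", {
  cv <- unit_cov()
  # the null latent covariance: 0.4 - 0.5 * 0.8 = 0 exactly
  p <- dependence_params(0.4, 0.5, 0.8, cv)
  expect_identical(lvm_rho(p, cv), 0.4 - 0.5 * 0.8)
  expect_equal(lvm_rho_grad(p, cv), c(1, -0.8, -0.5), tolerance = 1e-12)
  # the alternative covariance at theta = 0.2
  p2 <- dependence_params(0.2, 0.1, 0.1, cv)
  expect_equal(lvm_rho(p2, cv), 0.19, tolerance = 1e-12)
  # zeta-free reduction
  expect_equal(lvm_rho(dependence_params(0.33)), 0.33)
  expect_equal(lvm_rho_grad(dependence_params(0.33)), 1)
  # gradient vs finite differences on random feasible parameters
  set.seed(49)
  for (i in 1:5) {
    par <- runif(3, -0.5, 0.5)
    pp <- dependence_params(par[1], par[2], par[3], cv)
    fd <- vapply(1:3, function(j) {
      h <- 1e-7
      up <- dn <- par
      up[j] <- up[j] + h
      dn[j] <- dn[j] - h
      (lvm_rho(dependence_params(up[1], up[2], up[3]), cv) -
         lvm_rho(dependence_params(dn[1], dn[2], dn[3]), cv)) / (2 * h)
    }, numeric(1))
    expect_equal(lvm_rho_grad(pp, cv), fd, tolerance = 1e-7)
  }
})

test_that("Wald statistic identities hold", {
  V <- diag(3) * 2
  g <- c(1, -0.3, 0.2)
  w0 <- wald_test(0, g, V, 500)
  expect_identical(w0$TW, 0)
  expect_identical(w0$p_value, 1)
  w1 <- wald_test(0.1, g, V, 400)
  w2 <- wald_test(0.1, g, V, 800)
  expect_equal(w2$TW / w1$TW, sqrt(2), tolerance = 1e-12)
  expect_error(wald_test(0.1, g, -V, 400), "nonpositive")
})

test_that("the GEE solution matches a grid-search polychoric oracle on a
           2x2 table", {
  counts <- matrix(c(48, 14, 11, 27), 2, byrow = TRUE)
  gy <- counts_to_sample(counts)
  xi <- estimate_thresholds(rowSums(counts))
  eta <- estimate_thresholds(colSums(counts))
  oracle <- grid_polychoric(counts, xi, eta)
  d <- data.frame(g = gy$g, y = gy$y)
  s <- ordinal_sample(d, covariates = character(0))
  sol <- solve_gee(s)
  expect_equal(sol$params$delta12, oracle, tolerance = 1e-4)
  # the orchestrated covariate-free test reduces to rho = delta12
  fit <- lvm_test(d, allow_no_covariates = TRUE)
  expect_equal(fit$rho_hat, sol$params$delta12, tolerance = 1e-10)
})

test_that("the GEE solution matches an independent grid maximization with
           one covariate", {
  d <- simulate_ordinal(sim_config("nd", n = 250, maf = 0.4,
                                   genetic_model = "dominant", seed = 50))
  s <- ordinal_sample(d)
  sol <- solve_gee(s)
  ctx <- sol$ctx
  ref <- iterated_grid_max(s$g, s$y, s$Z, ctx$xi, ctx$eta, ctx$cov22)
  expect_equal(sol$par, ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("the summed score vanishes at every converged solution", {
  for (seed in c(51, 52, 53)) {
    d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.2,
                                     effect = -0.2, seed = seed))
    sol <- solve_gee(ordinal_sample(d))
    expect_true(sol$converged)
    expect_lt(max(abs(sol$mean_score)), 1e-6)
  }
})

test_that("estimates recover the generating dependence parameters and the
           null configuration at large n", {
  d <- simulate_ordinal(sim_config("nd", n = 2e5, maf = 0.3, seed = 54))
  sol <- solve_gee(ordinal_sample(d))
  expect_equal(sol$par, c(0.4, 0.5, 0.8), tolerance = 0.011,
               ignore_attr = TRUE)
})

test_that("estimation error shrinks with sample size", {
  err <- vapply(c(300, 3000, 30000), function(n) {
    e <- vapply(1:5, function(r) {
      d <- simulate_ordinal(sim_config("nd", n = n, maf = 0.3,
                                       seed = 7000 + 13 * r + n))
      max(abs(solve_gee(ordinal_sample(d))$par - c(0.4, 0.5, 0.8)))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(err[2] < err[1] && err[3] < err[2])
})

test_that("sandwich components are well-behaved and step-robust", {
  d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.3, seed = 55))
  sol <- solve_gee(ordinal_sample(d))
  sw5 <- sandwich_variance(sol$ctx, sol$par, fd_step = 1e-5)
  sw4 <- sandwich_variance(sol$ctx, sol$par, fd_step = 1e-4)
  expect_gt(min(eigen(sw5$I_mat, symmetric = TRUE)$values), -1e-10)
  expect_equal(sw5$V, t(sw5$V))
  expect_equal(sw5$J_mat, sw4$J_mat, tolerance = 1e-3)
})

test_that("the full test is deterministic and respects ordinal relabeling", {
  d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.3, effect = -0.2,
                                   seed = 56))
  f1 <- lvm_test(d)
  f2 <- lvm_test(d)
  expect_identical(f1$TW, f2$TW)
  # reversing the phenotype order flips the statistic's sign
  drev <- d
  drev$y <- max(d$y) + 1L - d$y
  f3 <- lvm_test(drev)
  expect_equal(f3$TW, -f1$TW, tolerance = 1e-6)
  # any strictly increasing relabeling leaves the statistic unchanged
  dmono <- d
  dmono$y <- c(2L, 5L, 11L, 17L, 23L)[d$y]
  expect_equal(lvm_test(dmono)$TW, f1$TW, tolerance = 1e-10)
})

test_that("zero-covariate input is rejected on the main path", {
  d <- simulate_ordinal(sim_config("nd", n = 200, maf = 0.3, seed = 57))
  expect_error(lvm_test(d[, c("g", "y")]), "covariate")
})

test_that("tidy and glance expose the fit in broom form", {
  d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.3, seed = 58))
  fit <- lvm_test(d)
  td <- tidy(fit)
  expect_identical(td$term, c("delta12", "zeta1_1", "zeta2_1"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$statistic, fit$rho_hat / fit$se_rho)
  expect_equal(gl$p.value, 2 * pnorm(-abs(gl$statistic)))
})
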