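test_that("analytic score matches finite differences of the composite
           objective on randomized feasible parameters", {
  set.seed(47)
  d <- simulate_ordinal(sim_config("nd", n = 80, maf = 0.3, seed = 101))
  s <- ordinal_sample(d)
  xi <- estimate_thresholds(tabulate(s$g + 1L))
  eta <- estimate_thresholds(tabulate(s$y))
  cv <- estimate_cov22(s$Z)
  for (rep in 1:8) {
    par <- runif(3, -0.6, 0.6)
    dp <- list(delta12 = par[1], zeta1 = par[2], zeta2 = par[3])
    analytic <- colSums(score_phi(s$g, s$y, s$Z, dp, xi, eta, cv))
    fd <- vapply(1:3, function(j) {
      h <- 1e-6
      ep <- em <- par
      ep[j] <- ep[j] + h
      em[j] <- em[j] - h
      (composite_h(s$g, s$y, s$Z, ep, xi, eta, cv) -
         composite_h(s$g, s$y, s$Z, em, xi, eta, cv)) / (2 * h)
    }, numeric(1))
    expect_equal(analytic, fd, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("the correlation derivative identity holds at the origin", {
  # Plackett: d Phi2(0,0;rho)/d rho at rho = 0 is 1/(2 pi)
  fd <- (pbvn(0, 0, 1e-7) - pbvn(0, 0, -1e-7)) / 2e-7
  expect_equal(fd, 1 / (2 * pi), tolerance = 1e-6)
  expect_equal(dbvn(0, 0, 0), 1 / (2 * pi), tolerance = 1e-14)
})

test_that("the score is centered at the generating parameters", {
  d <- simulate_ordinal(sim_config("nd", n = 1e5, maf = 0.3, seed = 48))
  s <- ordinal_sample(d)
  xi <- estimate_thresholds(tabulate(s$g + 1L))
  eta <- estimate_thresholds(tabulate(s$y))
  cv <- estimate_cov22(s$Z)
  truth <- list(delta12 = 0.4, zeta1 = 0.5, zeta2 = 0.8)
  ms <- colMeans(score_phi(s$g, s$y, s$Z, truth, xi, eta, cv))
  expect_lt(max(abs(ms)), 0.01)
})
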