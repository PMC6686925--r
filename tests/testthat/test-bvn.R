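test_that("orthant probabilities follow the arcsine formula", {
  for (rho in c(-0.9, -0.5, 0, 0.3, 0.5, 0.95)) {
    expect_equal(pbvn(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-12)
  }
  expect_equal(bvn_rect_prob(-Inf, 0, -Inf, 0, rho = 0.5), 1 / 3,
               tolerance = 1e-12)
})

test_that("zero correlation factorizes into univariate margins", {
  set.seed(41)
  for (i in 1:20) {
    a <- sort(rnorm(2, sd = 2))
    b <- sort(rnorm(2, sd = 2))
    expect_equal(bvn_rect_prob(a[1], a[2], b[1], b[2], rho = 0),
                 diff(pnorm(a)) * diff(pnorm(b)), tolerance = 1e-12)
  }
})

test_that("CDF matches the deterministic reference across both branches", {
  set.seed(42)
  for (i in 1:120) {
    rho <- runif(1, -0.9999, 0.9999)
    h <- rnorm(1, sd = 2.5)
    k <- rnorm(1, sd = 2.5)
    expect_equal(pbvn(h, k, rho), ref_pbvn(h, k, rho), tolerance = 1e-10)
  }
  # extreme correlations explicitly
  for (rho in c(-0.99999, -0.95, 0.93, 0.99999)) {
    expect_equal(pbvn(0.7, -0.3, rho), ref_pbvn(0.7, -0.3, rho),
                 tolerance = 1e-9)
  }
})

test_that("rectangle probabilities over a full partition sum to one", {
  set.seed(43)
  for (rho in c(-0.7, 0.3)) {
    xs <- c(-Inf, sort(rnorm(3)), Inf)
    ys <- c(-Inf, sort(rnorm(4)), Inf)
    tot <- 0
    for (i in 1:(length(xs) - 1)) {
      for (j in 1:(length(ys) - 1)) {
        tot <- tot + bvn_rect_prob(xs[i], xs[i + 1], ys[j], ys[j + 1], rho)
      }
    }
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("dbvn is the correlation derivative of the CDF", {
  expect_equal(dbvn(0, 0, 0), 1 / (2 * pi), tolerance = 1e-12)
  set.seed(44)
  for (i in 1:10) {
    rho <- runif(1, -0.8, 0.8)
    h <- rnorm(1)
    k <- rnorm(1)
    fd <- (pbvn(h, k, rho + 1e-6) - pbvn(h, k, rho - 1e-6)) / 2e-6
    expect_equal(dbvn(h, k, rho), fd, tolerance = 1e-6)
  }
  expect_equal(dbvn(Inf, 0, 0.3), 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(pbvn(0, 0, 1), "rho")
  expect_error(bvn_rect_prob(1, 0, -Inf, 0, rho = 0.2), "lower < upper")
})
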