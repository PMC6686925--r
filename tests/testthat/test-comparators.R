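test_that("cumulative-link fits recover a generative proportional-odds
           effect", {
  d <- simulate_ordinal(sim_config("po", n = 3000, maf = 0.3, effect = 5,
                                   seed = 60))
  for (m in c("logit", "probit")) {
    fit <- ordinal_reg_test(d, model = m)
    expect_true(fit$converged)
    expect_gt(fit$z, 2)
    expect_equal(fit$z, fit$beta_g / fit$se_g)
    expect_equal(fit$p_value, 2 * pnorm(-abs(fit$z)))
  }
})

test_that("probit and logit agree in sign on clear signals", {
  set.seed(61)
  for (r in 1:10) {
    d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.3,
                                     effect = sample(c(-0.2, 0.2), 1),
                                     seed = 600 + r))
    zp <- ordinal_reg_test(d, "probit")$z
    zl <- ordinal_reg_test(d, "logit")$z
    if (is.finite(zp) && is.finite(zl) && abs(zp) > 0.5) {
      expect_identical(sign(zp), sign(zl))
    }
  }
})

test_that("fitted cumulative probabilities are monotone across levels", {
  d <- simulate_ordinal(sim_config("po", n = 400, maf = 0.3, effect = 5,
                                   seed = 62))
  fit <- ordinal_reg_test(d, "logit")
  cp <- ordlvm:::.ordreg_cumprobs(fit)
  expect_true(all(apply(cp, 1, function(x) all(diff(x) >= -1e-12))))
  expect_equal(unname(cp[, ncol(cp)]), rep(1, nrow(cp)), tolerance = 1e-8)
})

test_that("a failed fit is flagged, not raised", {
  d <- data.frame(g = rep(1, 40), y = rep(1:2, 20), z = rnorm(40))
  fit <- ordinal_reg_test(d, "logit")
  expect_false(fit$converged)
  expect_true(is.na(fit$p_value))
})

test_that("p-values are uniform under a permutation null", {
  d <- simulate_ordinal(sim_config("po", n = 300, maf = 0.3, effect = 5,
                                   seed = 63))
  set.seed(64)
  pv <- vapply(1:300, function(i) {
    dp <- d
    dp$g <- sample(dp$g)
    ordinal_reg_test(dp, "logit")$p_value
  }, numeric(1))
  pv <- pv[is.finite(pv)]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
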