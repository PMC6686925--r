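test_that("genotype cell probabilities and codings are correct", {
  cfg <- sim_config("nd", maf = 0.3)
  expect_equal(genotype_cell_probs(cfg)$probs, c(0.49, 0.42, 0.09))
  cfg2 <- sim_config("nd", "recessive", probs = c(0.2, 0.7, 0.1))
  gp <- genotype_cell_probs(cfg2)
  expect_identical(gp$coding, c(0L, 0L, 1L))
  expect_equal(unname(gp$coded_probs), c(0.9, 0.1))
  # the sparse case behind the unavailable grid cells
  gp3 <- genotype_cell_probs(sim_config("nd", "recessive", maf = 0.1))
  expect_equal(unname(gp3$coded_probs[2]), 0.01)
  expect_identical(genotype_cell_probs(
    sim_config("nd", "dominant", maf = 0.2))$coding, c(0L, 1L, 1L))
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config("nd"), "exactly one")
  expect_error(sim_config("nd", maf = 0.3, probs = c(0.2, 0.3, 0.5)),
               "exactly one")
  expect_error(sim_config("nd", maf = 0.7), "maf")
  expect_error(sim_config("nd", probs = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(sim_config("po", maf = 0.2, effect = -1), "nonnegative")
})

test_that("the latent covariance has the stated structure", {
  S1 <- ordlvm:::.nd_sigma(NULL)
  expect_equal(S1[upper.tri(S1)], c(0.4, 0.5, 0.8))
  expect_equal(0.4 - 0.5 * 0.8, 0) # the null identity behind Sigma1
  S2 <- ordlvm:::.nd_sigma(-0.2)
  expect_equal(S2[upper.tri(S2)], c(-0.2, 0.1, 0.1))
  expect_equal(diag(S2), rep(1, 3))
})

test_that("generation is reproducible under a seed", {
  for (mech in c("nd", "po")) {
    cfg <- sim_config(mech, n = 200, maf = 0.3, effect = if (mech == "po") 5
                      else 0.2, seed = 65)
    expect_identical(simulate_ordinal(cfg), simulate_ordinal(cfg))
  }
})

test_that("ND category frequencies converge to their targets", {
  n <- 1e5
  d <- simulate_ordinal(sim_config("nd", n = n, maf = 0.3, seed = 66))
  fy <- tabulate(d$y, 5) / n
  target_y <- c(0.7, 0.1, 0.08, 0.07, 0.05)
  expect_true(all(abs(fy - target_y) <
                    3 * sqrt(target_y * (1 - target_y) / n)))
  fg <- tabulate(d$g + 1L, 3) / n
  target_g <- c(0.49, 0.42, 0.09)
  expect_true(all(abs(fg - target_g) <
                    3 * sqrt(target_g * (1 - target_g) / n)))
})

test_that("PO marginals match numeric integration of the cumulative logit", {
  n <- 2e5
  d <- simulate_ordinal(sim_config("po", n = n, maf = 0.3, seed = 67))
  # Pr(Y <= 1) = E_Z plogis(0.85 - Z), and plogis(0.85) ~ 0.7006 at Z = 0
  p1 <- integrate(function(z) plogis(0.85 - z) * dnorm(z), -Inf, Inf)$value
  expect_equal(mean(d$y == 1), p1, tolerance = 3 * sqrt(0.25 / n) / p1)
  expect_equal(plogis(0.85), 0.7006, tolerance = 1e-4)
  # effects scale as v * (0, 0.15, 0.3)
  cfg <- sim_config("po", maf = 0.3, effect = 5)
  expect_equal(cfg$effect * cfg$beta_scale, c(0, 0.75, 1.5))
})

test_that("PO with v = 0 makes phenotype independent of genotype", {
  d <- simulate_ordinal(sim_config("po", n = 5e4, maf = 0.3, seed = 68))
  expect_gt(suppressWarnings(chisq.test(table(d$g, d$y)))$p.value, 0.001)
})
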