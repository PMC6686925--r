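test_that("the scenario grid enumerates the full study design", {
  sizes <- vapply(1:4, function(t) nrow(scenario_grid(t)), integer(1))
  expect_identical(sizes, c(75L, 45L, 30L, 18L))
  expect_identical(sum(sizes), 168L)
  expect_identical(anyDuplicated(dplyr::bind_rows(
    lapply(1:4, scenario_grid))$scenario), 0L)
})

test_that("rejection bookkeeping behaves at the edges", {
  cfg <- sim_config("nd", n = 150, maf = 0.4, effect = 0.2)
  # alpha = 1 rejects everything
  r <- run_scenario(cfg, methods = "lvm", alpha = 1, reps = 3, seed = 70)
  expect_equal(r$rejection_rate, 1)
  expect_equal(r$mc_se, 0)
  # seeded determinism
  r1 <- run_scenario(cfg, methods = "lvm", reps = 10, seed = 71)
  r2 <- run_scenario(cfg, methods = "lvm", reps = 10, seed = 71)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
})

test_that("sparse recessive scenarios are reported unavailable", {
  cfg <- sim_config("nd", "recessive", maf = 0.1, n = 300)
  r <- run_scenario(cfg, methods = "lvm", reps = 5, seed = 72)
  expect_false(r$available)
  expect_true(is.na(r$rejection_rate))
  # matching the blank pattern of the published grid
  g <- scenario_grid(1)
  avail <- vapply(seq_len(nrow(g)), function(i)
    ordlvm:::.scenario_available(ordlvm:::.grid_config(g[i, ])), logical(1))
  expect_identical(g$scenario[!avail],
                   g$scenario[g$model == "recessive" & g$dist == "0.1"])
})

test_that("reproduce_table runs end to end and attaches reference rates", {
  res <- reproduce_table(4, reps = 2, seed = 73, methods = "lvm")
  expect_s3_class(res, "lvm_rejection_tbl")
  expect_identical(nrow(res), 18L)
  expect_true(all(res$rejection_rate[res$available] %in% c(0, 0.5, 1)))
  expect_true(all(!is.na(res$reference[res$available])))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("power increases with the magnitude of the latent correlation", {
  pow <- vapply(c(0.1, 0.2), function(th) {
    cfg <- sim_config("nd", n = 300, maf = 0.3, effect = th)
    run_scenario(cfg, methods = "lvm", reps = 120, seed = 74)$rejection_rate
  }, numeric(1))
  se <- sqrt(pow * (1 - pow) / 120)
  expect_gt(pow[2], pow[1] + 2 * sqrt(sum(se^2)) - 0.1)
  expect_gt(pow[2], pow[1]) # |rho| = 0.19 vs 0.09
})
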