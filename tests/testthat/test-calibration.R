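test_that("calibration designs encode groups, cycle, and batches", {
  # mock-study shape: 11 communities + cycle + 4 machines -> 15 covariates
  withr::with_seed(40, {
    md <- tibble::tibble(
      sample_id = paste0("s", 1:30),
      group = c(rep("mock_0", 20), paste0("mock_", rep(1:10, 1))),
      cycle = c(rep(c(10, 15, 20, 25, 30), 4), rep(35, 10)),
      batch = paste0("machine_", rep_len(1:4, 30)))
  })
  cd <- build_design(md)
  expect_equal(nrow(cd$design$x), 15)
  expect_equal(cd$design$roles,
               c(rep("group_intercept", 11), "cycle", rep("batch", 3)))
  # a calibration sample: group mock_0, cycle 20, machine 1 (reference)
  i <- which(md$group == "mock_0" & md$cycle == 20 & md$batch == "machine_1")[1]
  expect_equal(unname(cd$design$x[, i]),
               c(1, rep(0, 10), 20, 0, 0, 0))
  # human-study shape: 4 persons + cycle + 5 machines -> 9 covariates
  md_h <- tibble::tibble(
    sample_id = paste0("h", 1:6),
    group = paste0("person_", c(1, 2, 3, 4, 2, 1)),
    cycle = c(20, 25, 30, 35, 25, 20),
    batch = paste0("machine_", c(1, 2, 3, 4, 4, 5)))
  cd_h <- build_design(md_h)
  expect_equal(nrow(cd_h$design$x), 9)
  # person 2, cycle 25, machine 4 -> (0,1,0,0, 25, 0,0,1,0)
  expect_equal(unname(cd_h$design$x[, 5]), c(0, 1, 0, 0, 25, 0, 0, 1, 0))
  # two samples differing only in cycle differ only in the cycle entry
  md2 <- tibble::tibble(sample_id = c("a", "b"), group = "g",
                        cycle = c(10, 30), batch = "m1")
  X2 <- build_design(md2)$design$x
  expect_equal(unname(which(X2[, 1] != X2[, 2])), 2L)
  expect_error(build_design(md2, groups = "other"), "unknown group")
})

test_that("two-taxon bias estimation matches the log-ratio regression", {
  cfg <- calibration_config(D = 2, true_a = c(0.5, 0.5), true_b = c(2, 1.8),
                            cycles = c(10, 15, 20, 25, 30, 35),
                            replicates_per_cycle = 3, depth = 1e6,
                            noise_sigma = 0, seed = 5)
  sim <- simulate_calibration(cfg)
  b_ratio <- sim$truth$b[1] / sim$truth$b[2]
  cd <- build_design(sim$metadata)
  bias <- estimate_bias(sim$counts, cd, n_draws = 2000, seed = 2)
  bhat <- mean(bias$beta_draws)
  expect_equal(bhat, unname(log(b_ratio)), tolerance = 0.02)
  lr <- log(unclass(sim$counts)[1, ] / unclass(sim$counts)[2, ])
  ols <- unname(stats::coef(stats::lm(lr ~ sim$metadata$cycle))[2])
  expect_equal(bhat, ols, tolerance = 0.01)
})

test_that("equal efficiencies give a slope concentrated at zero", {
  cfg <- calibration_config(D = 4, true_b = rep(2, 4),
                            cycles = c(10, 20, 30), replicates_per_cycle = 3,
                            depth = 5e4, noise_sigma = 0, seed = 6)
  sim <- simulate_calibration(cfg)
  bias <- estimate_bias(sim$counts, build_design(sim$metadata),
                        n_draws = 500, seed = 3)
  cs <- credible_summary(bias$beta_draws)
  expect_true(all(abs(cs$mean) < 0.003))
  expect_true(all(!cs$excludes_zero))
})

test_that("a single cycle value is rejected as unidentifiable", {
  sim <- small_calibration(D = 3, cycles = 20, reps = 4, seed = 7)
  expect_error(estimate_bias(sim$counts, build_design(sim$metadata)),
               "2 distinct cycle")
})

test_that("composition_at_cycle follows the two-template closed form", {
  basis <- alr_basis(2)
  S <- 50
  bias <- make_bias(alpha = array(0, c(1, 1, S)),
                    beta = matrix(log(1.1), 1, S), basis = basis)
  p10 <- composition_at_cycle(bias, "g1", 10)
  expect_equal(unname(p10[1, ] / p10[2, ]), rep(1.1^10, S),
               tolerance = 1e-9)
  expect_equal(unname(1.1^10), 2.5937, tolerance = 1e-4)
  # x = 0 is exactly the intercept composition
  p0 <- composition_at_cycle(bias, "g1", 0)
  expect_equal(unname(p0[, 1]), from_logratio(0, basis))
  # zero slope: identical at all cycles
  bias0 <- make_bias(array(c(0.3, -0.2), c(2, 1, 4)),
                     matrix(0, 2, 4), alr_basis(3))
  expect_equal(composition_at_cycle(bias0, "g1", 0),
               composition_at_cycle(bias0, "g1", 35))
  expect_error(composition_at_cycle(bias0, "nope", 0), "unknown group")
})

test_that("fold-change and CLR bias summaries are mutually consistent", {
  withr::with_seed(41, {
    basis <- alr_basis(5)
    S <- 20
    alpha <- array(rnorm(4 * S, sd = 0.5), c(4, 1, S))
    beta <- matrix(rnorm(4 * S, sd = 0.02), 4, S)
  })
  bias <- make_bias(alpha, beta, basis)
  # log2 fold via compositions vs direct definition
  fc <- bias_fold_change(bias, "g1", 35)
  p35 <- composition_at_cycle(bias, "g1", 35)
  p0 <- composition_at_cycle(bias, "g1", 0)
  expect_equal(fc, log2(p35) - log2(p0), tolerance = 1e-9)
  # worked example: proportion 0.1 -> 0.4 is +2 on the log2 scale
  expect_equal(log2(0.4) - log2(0.1), 2)
  # CLR bias equals the CLR representation of x * beta, sums to zero,
  # and is exactly linear in x
  bc <- bias_clr(bias, 35)
  expect_equal(bc, alr_to_clr(35 * beta, basis), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colSums(bc), rep(0, S), tolerance = 1e-9)
  expect_equal(bias_clr(bias, 35), 35 * bias_clr(bias, 1),
               tolerance = 1e-9)
  # zero slope: zero bias on both scales
  bias0 <- make_bias(alpha, 0 * beta, basis)
  expect_equal(max(abs(bias_fold_change(bias0, "g1", 35))), 0)
  expect_equal(max(abs(bias_clr(bias0, 35))), 0)
})

test_that("correction inverts the accumulated perturbation", {
  basis <- alr_basis(2)
  S <- 10
  bias <- make_bias(array(0, c(1, 1, S)), matrix(log(2), 1, S), basis)
  # observed 8:1 after 3 cycles of 2-fold-per-cycle bias -> 1:1
  corr <- correct_composition(c(8 / 9, 1 / 9), bias, x = 3)
  expect_equal(unname(corr[, 1]), c(0.5, 0.5), tolerance = 1e-9)
  # beta = 0 is the identity
  bias0 <- make_bias(array(0, c(2, 1, S)), matrix(0, 2, S), alr_basis(3))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(unname(correct_composition(p, bias0, 35)[, 1]), p,
               tolerance = 1e-12)
  # zeros are a usage error pointing to the model-based route
  expect_error(correct_composition(c(0, 0.5, 0.5), bias0, 35),
               "composition_at_cycle")
  expect_error(correct_composition(p, bias0), "number of PCR cycles")
})

test_that("reference correction is exact by construction and isometric", {
  withr::with_seed(42, {
    D <- 5; S <- 200
    ref <- rand_comp(D)
    draws <- sapply(seq_len(S), function(s) closure(ref * rgamma(D, 50)))
  })
  delta <- reference_correction(draws, ref)
  # applying delta to the posterior mean (CLR) recovers the reference
  mean_clr <- rowMeans(clr(draws))
  expect_equal(closure(exp(mean_clr + delta)), ref, tolerance = 1e-9)
  corrected <- apply_reference_correction(draws, delta)
  # pairwise Aitchison distances are unchanged (perturbation isometry)
  for (pair in list(c(1, 2), c(3, 4), c(5, 6))) {
    expect_equal(
      aitchison_distance(corrected[, pair[1]], corrected[, pair[2]]),
      aitchison_distance(draws[, pair[1]], draws[, pair[2]]),
      tolerance = 1e-9)
  }
  # reference equal to the inferred mean -> delta = 0
  mean_comp <- closure(exp(mean_clr))
  d0 <- reference_correction(draws, mean_comp)
  expect_equal(unname(d0), rep(0, D), tolerance = 1e-9)
  expect_error(reference_correction(draws, rand_comp(4)), "mismatch")
})

test_that("slope posteriors tighten with replication", {
  sds <- sapply(c(1, 4), function(reps) {
    sim <- small_calibration(D = 3, cycles = c(10, 20, 30), reps = reps,
                             depth = 5e3, noise = 0.1, seed = 8)
    bias <- estimate_bias(sim$counts, build_design(sim$metadata),
                          n_draws = 1000, seed = 4)
    mean(apply(bias$beta_draws, 1, sd))
  })
  # 4x replication should roughly halve the posterior SD
  expect_lt(sds[2], 0.75 * sds[1])
})
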