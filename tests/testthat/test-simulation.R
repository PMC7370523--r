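test_that("reference normal moments follow the printed closed forms", {
  # symmetric mixture, w = 2: D* = diag(0, 4) + V
  cfg <- scenario_config(1, 2, replicates = 1)
  ref <- reference_normal(cfg)
  expect_equal(ref$mean, c(0, 0))
  expect_equal(ref$cov, matrix(c(1, 0.9, 0.9, 5), 2))

  # heavy-tail scenario, v = 5: D* = (5/3) Gamma
  cfg3 <- scenario_config(3, 5, replicates = 1)
  expect_equal(reference_normal(cfg3)$cov, 5 / 3 * cfg3$Gamma)
  expect_error(scenario_config(3, 2), "df > 2")

  # trivariate mixture, zero separation: D* = V
  cfg4 <- scenario_config(4, 0, replicates = 1)
  expect_equal(reference_normal(cfg4)$cov, cfg4$V)

  # asymmetric mixture: (3/4) m1 m1' + (1/4) m2 m2' + V, centred at 0
  cfg2 <- scenario_config(2, 2, replicates = 1)
  ref2 <- reference_normal(cfg2)
  expect_equal(ref2$mean, c(0, 0))
  expect_equal(ref2$cov,
               0.75 * tcrossprod(c(0, -1)) + 0.25 * tcrossprod(c(0, 3)) +
                 matrix(c(2, 0.9, 0.9, 2), 2))
})

test_that("mixture separations match the scenario parameterization", {
  expect_equal(mixture_separation(scenario_config(1, 1, replicates = 1)), 2)
  expect_equal(mixture_separation(scenario_config(1, 3, replicates = 1)), 6)
  expect_equal(round(mixture_separation(scenario_config(4, 0.5, replicates = 1)), 1),
               1.4)
  expect_equal(mixture_separation(scenario_config(2, 1, replicates = 1)), 4)
  expect_error(mixture_separation(scenario_config(3, 3, replicates = 1)),
               "no mixture")
})

test_that("simulated random effects are moment-matched to their reference normal", {
  set.seed(314)
  n <- 1e5
  # symmetric mixture at w = 1: cov = [[1, .9], [.9, 2]]
  cfg <- scenario_config(1, 1, replicates = 1)
  tau <- simulate_random_effects(cfg, n)
  expect_equal(colMeans(tau), c(0, 0), tolerance = 0.02)
  expect_equal(unname(cov(tau)), matrix(c(1, 0.9, 0.9, 2), 2), tolerance = 0.05)

  # both arms share mean and covariance (the study's comparability construct)
  for (cfg in list(scenario_config(2, 3, replicates = 1),
                   scenario_config(4, 1.5, replicates = 1))) {
    ref <- reference_normal(cfg)
    tau_nn <- simulate_random_effects(cfg, n)
    tau_n <- simulate_random_effects(cfg, n, arm = "normal")
    expect_equal(colMeans(tau_nn), ref$mean, tolerance = 0.05)
    expect_equal(colMeans(tau_n), ref$mean, tolerance = 0.05)
    expect_equal(unname(cov(tau_nn)), unname(ref$cov), tolerance = 0.08)
    expect_equal(unname(cov(tau_n)), unname(ref$cov), tolerance = 0.08)
  }

  # heavy tails, v = 3: covariance 3 * Gamma (slow convergence, loose bound)
  cfg3 <- scenario_config(3, 3, replicates = 1)
  tau3 <- simulate_random_effects(cfg3, n)
  expect_equal(diag(cov(tau3)) / diag(3 * cfg3$Gamma), rep(1, 3),
               tolerance = 0.25)
})

test_that("datasets follow the visit grids and covariate frequency", {
  cfg6 <- scenario_config(1, 3, N = 50, n = 6, replicates = 1)
  set.seed(1)
  d6 <- simulate_dataset(cfg6)
  expect_equal(unique(split(d6$time, d6$patient_id))[[1]], c(0, 0, 1, 2, 3, 4))
  expect_equal(sum(d6$phase == "baseline"), 2 * 50)

  cfg4 <- scenario_config(1, 3, N = 50, n = 4, replicates = 1)
  d4 <- simulate_dataset(cfg4)
  expect_equal(unname(unlist(lapply(split(d4$time, d4$patient_id), identity)))[1:4],
               c(0, 0, 1, 4))

  cfgN <- scenario_config(1, 3, N = 5000, n = 4, replicates = 1)
  set.seed(2)
  dN <- simulate_dataset(cfgN)
  xfreq <- mean(covariate_groups(dN)$x)
  expect_equal(xfreq, 0.6, tolerance = 0.03)
})

test_that("dataset simulation is deterministic given the RNG state", {
  cfg <- scenario_config(2, 2, N = 20, n = 6, replicates = 1)
  set.seed(7); d1 <- simulate_dataset(cfg)
  set.seed(7); d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("scenario runs are reproducible and internally consistent", {
  cfg <- scenario_config(1, 3, N = 40, n = 4, replicates = 2, seed = 5)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$R, discrepancy_ratio(r1$table$omegabar_nonnormal,
                                       r1$table$omegabar_normal))
  expect_equal(unname(r1$representative["nonnormal"]),
               representative_replicate(r1$table$omegabar_nonnormal))
  det <- replicate_details(r1, 1, "nonnormal")
  expect_equal(det$cvm$omega_bar, r1$table$omegabar_nonnormal[1])
})

test_that("a null control (mixture collapsed onto its reference) gives R near 1", {
  # w = 0 makes the 'non-normal' mixture exactly the reference normal
  cfg <- scenario_config(1, 0, N = 60, n = 4, replicates = 20, seed = 77)
  res <- run_scenario(cfg)
  omega <- res$table
  se_r <- res$R * sqrt(var(omega$omegabar_nonnormal) /
                         (20 * mean(omega$omegabar_nonnormal)^2) +
                       var(omega$omegabar_normal) /
                         (20 * mean(omega$omegabar_normal)^2))
  expect_lt(abs(res$R - 1), 3 * se_r + 0.05)
})

test_that("sensitivity grows with the mixture separation (reduced replicates)", {
  rs <- vapply(c(1, 3, 5), function(w) {
    run_scenario(scenario_config(1, w, N = 100, n = 4, replicates = 25,
                                 seed = 400 + w))$R
  }, 0)
  expect_gt(rs[3], rs[1])
  expect_true(all(diff(rank(rs)) > 0) || cor(rs, c(1, 3, 5), method = "spearman") > 0)
})
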