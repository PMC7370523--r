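# Marginal Gaussian log-likelihood evaluated directly per patient from the
# model components (independent of the fitting code path).
marg_loglik <- function(data, spec, psi, Sigma, sigma2) {
  X <- benefitqq:::fixed_design(data, spec)
  r <- data$response - drop(X %*% psi)
  ll <- 0
  for (pid in attr(data, "patients")) {
    rows <- which(data$patient_id == pid)
    Z <- benefitqq:::random_design(data$time[rows], spec)
    V <- Z %*% Sigma %*% t(Z) + diag(sigma2, length(rows))
    R <- chol(V)
    z <- backsolve(R, r[rows], transpose = TRUE)
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(z^2))
  }
  ll
}

test_that("the noise-free limit recovers the generating fixed effects", {
  set.seed(42)
  sim <- sim_pm_data(N = 20, times = c(0, 0, 1, 2, 3, 4),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = diag(1e-10, 2), sigma = 1e-4)
  fit <- fit_relm(sim$data, relm_spec(2, c(0, 1)))
  expect_equal(unname(fit$psi), c(21, 2, -5, 0.5), tolerance = 1e-4)
})

test_that("ML log-likelihood matches a direct multivariate-normal evaluation", {
  set.seed(7)
  sim <- sim_pm_data(N = 12, times = c(0, 0, 1, 4),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = matrix(c(2, 0.5, 0.5, 1), 2), sigma = sqrt(10))
  spec <- relm_spec(2, c(0, 1), method = "ML")
  fit <- fit_relm(sim$data, spec)
  ll <- marg_loglik(sim$data, spec, fit$psi, fit$Sigma, fit$sigma2_eps)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  # optimizer sanity: achieved objective beats the generating parameters
  ll_true <- marg_loglik(sim$data, spec, c(21, 2, -5, 0.5),
                         matrix(c(2, 0.5, 0.5, 1), 2), 10)
  expect_gte(fit$loglik, ll_true)
})

test_that("BLUPs match hand matrix algebra and the Henderson-equation oracle", {
  # 2-patient toy with q = 2: everything written out explicitly
  times <- c(0, 0, 1, 4)
  df <- data.frame(patient_id = rep(1:2, each = 4),
                   phase = rep(c("baseline", "baseline", "treatment", "treatment"), 2),
                   time = rep(times, 2),
                   response = c(23.1, 20.4, 16.2, 4.9, 26.0, 24.3, 21.1, 12.8),
                   x = rep(c(1, 0), each = 4))
  d <- pm_data(df)
  Sigma <- matrix(c(3, 0.8, 0.8, 1.5), 2)
  fit <- fake_relm_fit(21, 2, c(-5, 0.5), Sigma, sigma2 = 10)
  eb <- predict_random_effects(fit, d)

  for (i in 1:2) {
    rows <- df[df$patient_id == i, ]
    X <- cbind(1, rows$x, times, times^2)
    Z <- cbind(1, times)
    V <- Z %*% Sigma %*% t(Z) + 10 * diag(4)
    resid <- rows$response - X %*% c(21, 2, -5, 0.5)
    tau_direct <- Sigma %*% t(Z) %*% solve(V) %*% resid
    expect_equal(unname(eb$tau[i, ]), drop(tau_direct), tolerance = 1e-10)
    # Henderson mixed-model equations with the fixed effects plugged in
    tau_h <- solve(crossprod(Z) + 10 * solve(Sigma), crossprod(Z, resid))
    expect_equal(unname(eb$tau[i, ]), unname(drop(tau_h)), tolerance = 1e-8)
  }
  expect_equal(unname(eb$Lambda), 21 + eb$tau[, 1] + 2 * c(1, 0),
               ignore_attr = TRUE)
})

test_that("EB prediction agrees with lme4's conditional modes on a real fit", {
  set.seed(11)
  sim <- sim_pm_data(N = 40, times = c(0, 0, 1, 2, 3, 4),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = matrix(c(2, 0.7, 0.7, 1.2), 2), sigma = sqrt(10))
  fit <- fit_relm(sim$data, relm_spec(2, c(0, 1)))
  eb <- predict_random_effects(fit, sim$data)

  d <- as.data.frame(sim$data)
  d$t2 <- d$time^2
  m <- lme4::lmer(response ~ x + time + t2 + (1 + time | patient_id), data = d,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  re <- lme4::ranef(m)$patient_id
  re <- re[match(rownames(eb$tau), rownames(re)), ]
  expect_equal(unname(eb$tau), unname(as.matrix(re)), tolerance = 1e-5)
  # BLUP shrinkage centering: weighted mean of tau_hat near 0
  expect_lt(max(abs(colMeans(eb$tau))), 0.5)
})

test_that("zero random-effect covariance gives zero BLUPs", {
  set.seed(3)
  sim <- sim_pm_data(N = 5, times = c(0, 0, 1, 4),
                     psi_int = 20, psi_cov = 1, psi_time = c(-4, 0.4),
                     Sigma = diag(2), sigma = 2)
  fit <- fake_relm_fit(20, 1, c(-4, 0.4), matrix(0, 2, 2), sigma2 = 4)
  eb <- predict_random_effects(fit, sim$data)
  expect_equal(unname(eb$tau), matrix(0, 5, 2))
})

test_that("EB prediction recovers the signal in the random slopes", {
  set.seed(21)
  sim <- sim_pm_data(N = 300, times = c(0, 0, 1, 2, 3, 4),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = matrix(c(2, 0.9, 0.9, 2), 2), sigma = sqrt(10))
  fit <- fit_relm(sim$data, relm_spec(2, c(0, 1)))
  eb <- predict_random_effects(fit, sim$data)
  expect_gt(cor(eb$tau[, 2], sim$tau[, 2]), 0.5)
  # shrinkage: predictions are less spread than the truth on average
  expect_lte(mean(abs(eb$tau[, 2])), max(abs(sim$tau[, 2])))
})

test_that("conditional residuals behave like the error term", {
  # many visits per patient: the BLUP absorbs only ~q/n of the error
  # variance, so the residual variance approaches sigma2_eps
  set.seed(13)
  sim <- sim_pm_data(N = 60, times = c(0, 0, seq_len(38)),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = matrix(c(2, 0.5, 0.5, 1), 2), sigma = sqrt(10))
  fit <- fit_relm(sim$data, relm_spec(2, c(0, 1)))
  eb <- predict_random_effects(fit, sim$data)
  res <- conditional_residuals(fit, eb, sim$data)
  expect_equal(nrow(res), nrow(sim$data))
  expect_lt(abs(var(res$residual) / fit$sigma2_eps - 1), 0.10)

  # per-patient locality: dropping a patient, fit held fixed, leaves the
  # other residuals unchanged
  keep <- as.data.frame(sim$data)[sim$data$patient_id != 1, ]
  d2 <- pm_data(keep, covariates = "x")
  eb2 <- predict_random_effects(fit, d2)
  res2 <- conditional_residuals(fit, eb2, d2)
  expect_equal(res2$residual, res$residual[res$patient_id != 1])

  # noise-free limit: residuals vanish
  sim0 <- sim_pm_data(N = 10, times = c(0, 0, 1, 4),
                      psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                      Sigma = diag(1e-12, 2), sigma = 1e-6)
  fit0 <- fake_relm_fit(21, 2, c(-5, 0.5), diag(1e-12, 2), sigma2 = 1e-12)
  eb0 <- predict_random_effects(fit0, sim0$data)
  res0 <- conditional_residuals(fit0, eb0, sim0$data)
  expect_lt(max(abs(res0$residual)), 1e-4)
})

test_that("bad inputs fail loudly", {
  set.seed(5)
  sim <- sim_pm_data(N = 10, times = c(0, 0, 1, 4),
                     psi_int = 21, psi_cov = 2, psi_time = c(-5, 0.5),
                     Sigma = diag(2), sigma = 1)
  df <- as.data.frame(sim$data)
  df$z <- df$x  # collinear duplicate covariate
  expect_error(fit_relm(pm_data(df), relm_spec(2, c(0, 1))),
               "rank deficient.*collinear")
  one <- pm_data(df[df$patient_id == 1, ])
  expect_error(fit_relm(one, relm_spec(2, c(0, 1))), "at least 2 patients")
  expect_error(relm_spec(2, c(1)), "must include 0")
  expect_error(relm_spec(2, c(0, 3)), "subset of 0:degree")
})
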