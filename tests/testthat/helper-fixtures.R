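# Shared fixtures: all data is generated in code at test time.

# A relm_fit object with known components, bypassing estimation, for testing
# the downstream algebra (BLUPs, benefit laws, BQQ construction) against
# hand-computed oracles.
fake_relm_fit <- function(psi_int, psi_cov, psi_time, Sigma, sigma2,
                          random_degrees = c(0, 1), covariates = "x",
                          method = "REML", max_time = 4) {
  degree <- length(psi_time)
  psi <- c(psi_int, psi_cov, psi_time)
  names(psi) <- c("(Intercept)", covariates,
                  paste0("time^", seq_len(degree)))
  rn <- ifelse(random_degrees == 0, "(Intercept)",
               paste0("time^", random_degrees))
  dimnames(Sigma) <- list(rn, rn)
  structure(list(psi = psi, Sigma = Sigma, sigma2_eps = sigma2,
                 loglik = NA_real_, converged = TRUE, singular = FALSE,
                 messages = character(0),
                 spec = relm_spec(degree = degree,
                                  random_degrees = random_degrees,
                                  method = method),
                 covariates = covariates, n_patients = NA_integer_,
                 max_time = max_time),
            class = "relm_fit")
}

# A benefit_sample built directly from benefit values (one binary covariate
# "x"), for exercising BQQ/CVM construction without a model fit.
make_benefit_sample <- function(benefits, x, t, y) {
  stopifnot(length(benefits) == length(x))
  lab <- as.character(x)
  df <- data.frame(patient_id = seq_along(benefits),
                   group = match(lab, sort(unique(lab))),
                   label = lab, basal_severity = 0.999,
                   benefit = benefits, time = t, x = x,
                   stringsAsFactors = FALSE)
  structure(df, t = t, y = y,
            group_sizes = as.integer(table(df$group)),
            class = c("benefit_sample", "data.frame"))
}

# Small longitudinal dataset simulated from explicit model components.
sim_pm_data <- function(N, times, psi_int, psi_cov, psi_time, Sigma, sigma,
                        x = stats::rbinom(N, 1, 0.6),
                        random_degrees = c(0, 1)) {
  q <- nrow(Sigma)
  tau <- matrix(MASS::mvrnorm(N, rep(0, q), Sigma), nrow = N)
  n <- length(times)
  phase <- ifelse(times == 0, "baseline", "treatment")
  rows <- lapply(seq_len(N), function(i) {
    fx <- psi_int + psi_cov * x[i] +
      colSums(psi_time * t(outer(times, seq_along(psi_time), `^`)))
    Z <- outer(times, random_degrees, `^`)
    Z[, random_degrees == 0] <- 1
    data.frame(patient_id = i, phase = phase, time = times,
               response = fx + drop(Z %*% tau[i, ]) + rnorm(n, 0, sigma),
               x = x[i])
  })
  list(data = pm_data(do.call(rbind, rows), covariates = "x"), tau = tau,
       x = x)
}
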