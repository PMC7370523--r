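#' Configuration of one simulation-study cell
#'
#' The simulation study probes the BQQ/CVM diagnostic with four families of
#' non-normal random-effect laws, each paired with a "reference" normal
#' distribution carrying the same mean and covariance:
#'
#' * **Scenario 1** (model 1, random intercept + linear slope): symmetric
#'   equal-weight mixture of two bivariate normals with means `w*(0,-1)` and
#'   `w*(0,1)` and common covariance `V = [[1, .9], [.9, 1]]`; `param = w` in
#'   1..5 controls the separation `2 w` of the component means.
#' * **Scenario 2** (model 1): asymmetric (3/4, 1/4) mixture with means
#'   `(0,-1)` and `(0,3)` and `V = [[s2, .9], [.9, s2]]`; `param = s2`
#'   (component variance) in 1..5 — larger values are less bimodal.
#' * **Scenario 3** (model 2, random intercept + linear + quadratic slopes):
#'   trivariate t with `param = v` degrees of freedom (3..13), location 0 and
#'   shape `Gamma`; smaller `v` means heavier tails.
#' * **Scenario 4** (model 2): symmetric mixture of two trivariate normals
#'   with means `w*(0,-1,1)` and `w*(0,1,-1)` and covariance `Gamma`;
#'   `param = w` in 0.5..3 gives separation `w*sqrt(8)`.
#'
#' Fixed effects, error variance 10, Bernoulli(0.6) covariate, target
#' `y = 7`, evaluation time `t = 4` and the visit grids (`n = 4`: times
#' 0,0,1,4; `n = 6`: times 0,0,1,2,3,4) are the study conditions shared by
#' all scenarios; the fixed effects differ per scenario and were chosen so
#' that nearly all simulated patients are severely ill.
#'
#' @param scenario 1, 2, 3 or 4.
#' @param param scenario parameter (`w`, component variance, or df `v`).
#' @param N number of patients.
#' @param n visits per patient, 4 or 6.
#' @param replicates number of simulation replicates per arm.
#' @param seed master seed for [run_scenario()].
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, param, N = 100, n = 6,
                            replicates = 500, seed = 1) {
  stopifnot(scenario %in% 1:4, n %in% c(4, 6), N >= 2, replicates >= 1)
  Gamma <- matrix(c(10.4, 0.279, -0.341,
                    0.279, 13.06, -2.466,
                    -0.341, -2.466, 0.581), 3, 3)
  cfg <- switch(as.character(scenario),
    "1" = list(model = 1, psi = c(21, 2, -5, 0.5),
               weights = c(0.5, 0.5),
               m1 = c(0, -1) * param, m2 = c(0, 1) * param,
               V = matrix(c(1, 0.9, 0.9, 1), 2, 2)),
    "2" = list(model = 1, psi = c(21, 2, -5, 0.5),
               weights = c(0.75, 0.25),
               m1 = c(0, -1), m2 = c(0, 3),
               V = matrix(c(param, 0.9, 0.9, param), 2, 2)),
    "3" = list(model = 2, psi = c(21.4, 1.92, -3.97, 0.35),
               df = param, m = c(0, 0, 0), Gamma = Gamma),
    "4" = list(model = 2, psi = c(24, 1.92, 0.97, -0.35),
               weights = c(0.5, 0.5),
               m1 = c(0, -1, 1) * param, m2 = c(0, 1, -1) * param,
               V = Gamma))
  if (scenario == 3 && param <= 2)
    stop("scenario 3 needs df > 2 (covariance, hence the reference normal, is undefined)")
  structure(c(list(scenario = scenario, param = param, N = N, n = n,
                   sigma2_eps = 10, covariate_prob = 0.6, y = 7, t_eval = 4,
                   replicates = replicates, seed = seed), cfg),
            class = "scenario_config")
}

#' Model specification for a scenario
#' @param cfg a [scenario_config].
#' @param method estimation method passed to [relm_spec()].
#' @return a [relm_spec]: degree-2 polynomial, random intercept + linear
#'   slope (model 1) or + quadratic slope (model 2).
#' @export
scenario_spec <- function(cfg, method = "REML") {
  relm_spec(degree = 2,
            random_degrees = if (cfg$model == 1) c(0, 1) else c(0, 1, 2),
            method = method)
}

#' Mean-separation of a mixture scenario
#'
#' Distance between the two component means: `2w` in scenario 1,
#' `||m1 - m2|| = 4` in scenario 2, and `w*sqrt(8)` in scenario 4.
#' Scenario 3 is not a mixture.
#'
#' @param cfg a [scenario_config].
#' @return the Euclidean distance between component means.
#' @export
mixture_separation <- function(cfg) {
  if (cfg$scenario == 3) stop("scenario 3 has no mixture components")
  sqrt(sum((cfg$m1 - cfg$m2)^2))
}

#' Moment-matched reference normal distribution
#'
#' Mean and covariance of the scenario's non-normal law, defining the
#' reference normal arm: for the equal-weight mixtures
#' `D* = m1 m1'/2 + m2 m2'/2 + V`, for the (3/4, 1/4) mixture
#' `D* = (3/4) m1 m1' + (1/4) m2 m2' + V`, and for the t distribution
#' `D* = v/(v-2) * Gamma` — each taken about the zero mean vector.
#'
#' @param cfg a [scenario_config].
#' @return list with `mean` and `cov`.
#' @export
reference_normal <- function(cfg) {
  if (cfg$scenario == 3) {
    list(mean = cfg$m, cov = cfg$df / (cfg$df - 2) * cfg$Gamma)
  } else {
    w <- cfg$weights
    list(mean = rep(0, length(cfg$m1)),
         cov = w[1] * tcrossprod(cfg$m1) + w[2] * tcrossprod(cfg$m2) + cfg$V)
  }
}

#' Draw random-effect vectors for a scenario arm
#'
#' Non-normal arm: the scenario's mixture or multivariate t law (the t is
#' built as `m + Z * sqrt(v / chisq_v)` with `Z ~ N(0, Gamma)`).  Normal arm:
#' the moment-matched reference normal.  Uses the current RNG state.
#'
#' @param cfg a [scenario_config].
#' @param N number of draws.
#' @param arm `"nonnormal"` or `"normal"`.
#' @return `N x q` matrix of random-effect vectors.
#' @export
simulate_random_effects <- function(cfg, N = cfg$N,
                                    arm = c("nonnormal", "normal")) {
  arm <- match.arg(arm)
  if (arm == "normal") {
    ref <- reference_normal(cfg)
    return(matrix(MASS::mvrnorm(N, ref$mean, ref$cov), nrow = N))
  }
  if (cfg$scenario == 3) {
    Z <- MASS::mvrnorm(N, rep(0, 3), cfg$Gamma)
    scale <- sqrt(cfg$df / stats::rchisq(N, df = cfg$df))
    return(matrix(rep(cfg$m, each = N) + Z * scale, nrow = N))
  }
  comp <- stats::rbinom(N, 1, cfg$weights[2])
  mu <- t(vapply(comp, function(c2) if (c2 == 1) cfg$m2 else cfg$m1,
                 numeric(length(cfg$m1))))
  mu + MASS::mvrnorm(N, rep(0, length(cfg$m1)), cfg$V)
}

#' Simulate one longitudinal dataset for a scenario arm
#'
#' Responses follow the scenario's degree-2 polynomial fixed effects with a
#' random intercept and linear slope (model 1) or additionally a random
#' quadratic slope (model 2), Bernoulli(0.6) binary covariate, N(0, 10)
#' errors, and the visit grid implied by `n` (first two visits baseline at
#' time 0).  Uses the current RNG state.
#'
#' @inheritParams simulate_random_effects
#' @return a [pm_data] with covariate column `x`.
#' @export
simulate_dataset <- function(cfg, arm = c("nonnormal", "normal")) {
  arm <- match.arg(arm)
  times <- if (cfg$n == 4) c(0, 0, 1, 4) else c(0, 0, 1, 2, 3, 4)
  phase <- c("baseline", "baseline", rep("treatment", cfg$n - 2))
  x <- stats::rbinom(cfg$N, 1, cfg$covariate_prob)
  tau <- simulate_random_effects(cfg, cfg$N, arm)
  psi <- cfg$psi
  rows <- vector("list", cfg$N)
  for (i in seq_len(cfg$N)) {
    ranpart <- tau[i, 1] + tau[i, 2] * times +
      if (cfg$model == 2) tau[i, 3] * times^2 else 0
    yy <- psi[1] + psi[2] * x[i] + psi[3] * times + psi[4] * times^2 +
      ranpart + stats::rnorm(cfg$n, 0, sqrt(cfg$sigma2_eps))
    rows[[i]] <- data.frame(patient_id = i, phase = phase, time = times,
                            response = yy, x = x[i])
  }
  pm_data(do.call(rbind, rows), covariates = "x")
}

child_seed <- function(seed, attempt) {
  as.integer((as.numeric(seed) + as.numeric(attempt) * 1000003) %% (2^31 - 1))
}

fit_omega_bar <- function(data, spec, y, t) {
  fit <- fit_relm(data, spec)
  if (!fit$converged) stop("fit did not converge")
  eb <- predict_random_effects(fit, data)
  sample <- eb_benefits(fit, eb, y = y, t = t, warn_threshold = 0)
  list(fit = fit, sample = sample, cvm = cvm_sample(sample, fit))
}

#' Run one simulation-study cell
#'
#' For each replicate and each arm (non-normal and moment-matched reference
#' normal): simulate a dataset, fit the scenario's model by REML, EB-predict
#' the individual benefits at `t = 4` with target `y = 7`, and compute the
#' weighted overall CVM discrepancy.  Replicates whose fit fails (optimizer
#' error, non-finite estimates, or a degenerate benefit law) are resimulated
#' with a fresh child seed, up to `max_retries` attempts, and counted.
#'
#' Seeding: the master `cfg$seed` draws one child seed per replicate-arm up
#' front; each simulation sets the RNG from its child seed, so arms and
#' replicates are reproducible independently.
#'
#' @param cfg a [scenario_config].
#' @param method estimation method (default REML).
#' @param max_retries resimulation attempts per replicate.
#' @return object of class `scenario_result`: list with `table` (one row per
#'   replicate: `rep`, `omegabar_nonnormal`, `omegabar_normal`),
#'   `omega_barbar` (per-arm means), `R` (sensitivity ratio),
#'   `representative` (per-arm replicate indices), `resimulations`, `cfg`.
#' @export
run_scenario <- function(cfg, method = "REML", max_retries = 25) {
  stopifnot(inherits(cfg, "scenario_config"))
  spec <- scenario_spec(cfg, method)
  set.seed(cfg$seed)
  seeds <- matrix(sample.int(2^31 - 2, 2 * cfg$replicates),
                  nrow = cfg$replicates, ncol = 2,
                  dimnames = list(NULL, c("nonnormal", "normal")))
  omega <- matrix(NA_real_, cfg$replicates, 2,
                  dimnames = list(NULL, c("nonnormal", "normal")))
  resim <- 0L
  for (r in seq_len(cfg$replicates)) {
    for (arm in c("nonnormal", "normal")) {
      for (attempt in 0:max_retries) {
        set.seed(child_seed(seeds[r, arm], attempt))
        res <- tryCatch(
          fit_omega_bar(simulate_dataset(cfg, arm), spec, cfg$y, cfg$t_eval),
          error = function(e) e)
        if (!inherits(res, "error")) break
        resim <- resim + 1L
      }
      if (inherits(res, "error"))
        stop("replicate ", r, " (", arm, " arm) failed after ",
             max_retries + 1, " attempts: ", conditionMessage(res))
      omega[r, arm] <- res$cvm$omega_bar
    }
  }
  tab <- data.frame(rep = seq_len(cfg$replicates),
                    omegabar_nonnormal = omega[, "nonnormal"],
                    omegabar_normal = omega[, "normal"])
  structure(list(table = tab,
                 omega_barbar = colMeans(omega),
                 R = discrepancy_ratio(omega[, "nonnormal"], omega[, "normal"]),
                 representative = c(
                   nonnormal = representative_replicate(omega[, "nonnormal"]),
                   normal = representative_replicate(omega[, "normal"])),
                 resimulations = resim, seeds = seeds, cfg = cfg),
            class = "scenario_result")
}

#' Reconstruct one replicate of a scenario run
#'
#' Re-runs the simulate/fit/benefit pipeline for a given replicate and arm of
#' a finished [run_scenario()] result (including the retry sequence), so that
#' e.g. the representative replicate's BQQ plot can be rendered.
#'
#' @param result a `scenario_result`.
#' @param rep replicate index.
#' @param arm `"nonnormal"` or `"normal"`.
#' @param method estimation method used in the original run.
#' @param max_retries as in [run_scenario()].
#' @return list with `fit`, `sample`, `cvm`, `points` (a `bqq_points`).
#' @export
replicate_details <- function(result, rep, arm = c("nonnormal", "normal"),
                              method = "REML", max_retries = 25) {
  stopifnot(inherits(result, "scenario_result"))
  arm <- match.arg(arm)
  cfg <- result$cfg
  spec <- scenario_spec(cfg, method)
  for (attempt in 0:max_retries) {
    set.seed(child_seed(result$seeds[rep, arm], attempt))
    res <- tryCatch(
      fit_omega_bar(simulate_dataset(cfg, arm), spec, cfg$y, cfg$t_eval),
      error = function(e) e)
    if (!inherits(res, "error")) break
  }
  if (inherits(res, "error")) stop(conditionMessage(res))
  res$points <- build_bqq(res$sample, res$fit)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$cfg
  cat("Scenario ", cfg$scenario, " (model ", cfg$model, "), param = ",
      cfg$param, ", N = ", cfg$N, ", n = ", cfg$n, ", ",
      cfg$replicates, " replicates/arm\n", sep = "")
  cat(sprintf("mean discrepancy: non-normal %.5f, reference normal %.5f\n",
              x$omega_barbar["nonnormal"], x$omega_barbar["normal"]))
  cat(sprintf("sensitivity ratio R = %.3f\n", x$R))
  if (x$resimulations > 0)
    cat("resimulated replicates after failed fits:", x$resimulations, "\n")
  invisible(x)
}
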