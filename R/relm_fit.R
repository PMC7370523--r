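#' Specify a random-effects linear model for treatment benefits
#'
#' The response is modelled as a patient-level intercept plus binary covariate
#' effects plus a degree-`d` polynomial in treatment time, with a subset of
#' the polynomial terms (always including the intercept) carrying random
#' effects with an unstructured covariance matrix, and homoscedastic Gaussian
#' errors.  `random_degrees = c(0, 1)` gives a random intercept and random
#' linear time slope; `c(0, 1, 2)` adds a random quadratic slope.
#'
#' @param degree fixed-effect time polynomial degree `d >= 1`.
#' @param random_degrees integer subset of `0:degree` carrying random effects;
#'   must include 0 (the intercept).
#' @param method `"REML"` (default) or `"ML"`.
#' @return an object of class `relm_spec`.
#' @export
relm_spec <- function(degree = 2, random_degrees = c(0, 1), method = c("REML", "ML")) {
  method <- match.arg(method)
  degree <- as.integer(degree)
  random_degrees <- sort(unique(as.integer(random_degrees)))
  if (degree < 1) stop("'degree' must be >= 1")
  if (!0 %in% random_degrees)
    stop("'random_degrees' must include 0: the intercept always carries a random effect")
  if (any(random_degrees < 0) || any(random_degrees > degree))
    stop("'random_degrees' must be a subset of 0:degree")
  structure(list(degree = degree, random_degrees = random_degrees, method = method),
            class = "relm_spec")
}

time_col <- function(deg) if (deg == 0) "(Intercept)" else paste0("time^", deg)

fixed_design <- function(data, spec) {
  cv <- attr(data, "covariates")
  X <- cbind(1, as.matrix(as.data.frame(data)[, cv, drop = FALSE]),
             outer(data$time, seq_len(spec$degree), `^`))
  colnames(X) <- c("(Intercept)", cv, vapply(seq_len(spec$degree), time_col, ""))
  X
}

random_design <- function(times, spec) {
  Z <- outer(times, spec$random_degrees, `^`)
  Z[, spec$random_degrees == 0] <- 1  # 0^0
  colnames(Z) <- vapply(spec$random_degrees, time_col, "")
  Z
}

#' Fit the random-effects linear model
#'
#' Estimates the fixed effects, the unstructured random-effect covariance
#' matrix and the error variance by REML or ML, via [lme4::lmer()].  The
#' marginal covariance of patient `w`'s responses is
#' `V_w = Z_w Sigma Z_w' + sigma_eps^2 I`.
#'
#' @param data a [pm_data] object.
#' @param spec a [relm_spec]; default degree-2 polynomial with random
#'   intercept and linear slope.
#' @return object of class `relm_fit` with elements `psi` (named fixed-effect
#'   vector, ordered intercept, covariates, time powers), `Sigma` (q x q),
#'   `sigma2_eps`, `loglik`, `converged`, `singular`, `messages`, `spec`,
#'   `covariates`, `n_patients`, `max_time`.
#' @export
fit_relm <- function(data, spec = relm_spec()) {
  stopifnot(inherits(data, "pm_data"), inherits(spec, "relm_spec"))
  patients <- attr(data, "patients")
  if (length(patients) < 2) stop("need at least 2 patients")
  tab <- table(data$patient_id)
  if (any(tab < 2)) stop("every patient needs at least 2 rows")

  X <- fixed_design(data, spec)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  cv <- attr(data, "covariates")
  d <- data.frame(.y = data$response, .id = factor(data$patient_id, levels = patients),
                  check.names = FALSE)
  for (nm in cv) d[[nm]] <- as.data.frame(data)[[nm]]
  for (k in seq_len(spec$degree)) d[[paste0(".t", k)]] <- data$time^k
  fterms <- c(cv, paste0(".t", seq_len(spec$degree)))
  rdeg <- setdiff(spec$random_degrees, 0)
  rterms <- c("1", if (length(rdeg)) paste0(".t", rdeg))
  fml <- stats::as.formula(paste(
    ".y ~", paste(fterms, collapse = " + "),
    "+ (", paste(rterms, collapse = " + "), "| .id)"))

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nRE = "ignore")
  caught <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = spec$method == "REML", control = ctrl),
    warning = function(w) {
      caught <<- c(caught, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  msgs <- unique(c(unlist(fit@optinfo$conv$lme4$messages), caught))
  converged <- fit@optinfo$conv$opt == 0 && all(is.finite(fit@theta))
  Sigma <- as.matrix(lme4::VarCorr(fit)[[".id"]])
  attr(Sigma, "stddev") <- attr(Sigma, "correlation") <- NULL
  q <- length(spec$random_degrees)
  rn <- vapply(spec$random_degrees, time_col, "")
  dimnames(Sigma) <- list(rn, rn)
  singular <- lme4::isSingular(fit)

  psi <- lme4::fixef(fit)
  names(psi) <- colnames(X)  # intercept, covariates, time^1..time^d

  structure(list(psi = psi, Sigma = Sigma, sigma2_eps = stats::sigma(fit)^2,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged, singular = singular,
                 messages = if (is.null(msgs)) character(0) else msgs,
                 spec = spec, covariates = cv,
                 n_patients = length(patients), max_time = max(data$time)),
            class = "relm_fit")
}

#' @export
print.relm_fit <- function(x, ...) {
  cat("Random-effects linear model (", x$spec$method, ")\n", sep = "")
  cat("fixed effects:\n"); print(round(x$psi, 4))
  cat("random-effect covariance Sigma:\n"); print(round(x$Sigma, 4))
  cat("error variance:", round(x$sigma2_eps, 4),
      " logLik:", round(x$loglik, 2), "\n")
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (x$singular) cat("note: Sigma estimate is on the boundary (singular)\n")
  invisible(x)
}

#' Empirical Bayes (BLUP) prediction of random effects
#'
#' Computes, for every patient, the estimated best linear unbiased predictor
#' `tau_w = Sigma Z_w' V_w^{-1} (y_w - X_w psi)` with the estimated variance
#' components plugged in, together with the patient's pre-treatment level
#' `Lambda_w = psi_0 + tau_{0,w} + psi_cov' x_w`.
#'
#' @param fit a [relm_fit].
#' @param data the [pm_data] the model was fitted to (or compatible data).
#' @return object of class `eb_pred`: `tau` (N x q matrix, one row per
#'   patient), `Lambda` (named vector), `x` (N x c covariate matrix), and the
#'   model pieces needed to evaluate per-patient treatment-effect curves.
#' @export
predict_random_effects <- function(fit, data) {
  stopifnot(inherits(fit, "relm_fit"), inherits(data, "pm_data"))
  if (!identical(attr(data, "covariates"), fit$covariates))
    stop("dataset covariates do not match the fitted model")
  spec <- fit$spec
  patients <- attr(data, "patients")
  X <- fixed_design(data, spec)
  resid_marg <- data$response - drop(X %*% fit$psi)
  q <- length(spec$random_degrees)
  tau <- matrix(0, length(patients), q,
                dimnames = list(as.character(patients), colnames(fit$Sigma)))
  idx <- split(seq_len(nrow(data)), match(data$patient_id, patients))
  for (i in seq_along(patients)) {
    rows <- idx[[i]]
    Z <- random_design(data$time[rows], spec)
    V <- Z %*% fit$Sigma %*% t(Z) + diag(fit$sigma2_eps, length(rows))
    if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("marginal covariance V is singular for patient ", patients[i])
    tau[i, ] <- drop(fit$Sigma %*% crossprod(Z, solve(V, resid_marg[rows])))
  }
  cg <- covariate_groups(data)
  xmat <- as.matrix(cg[, fit$covariates, drop = FALSE])
  Lambda <- fit$psi[1] + tau[, 1] +
    if (length(fit$covariates)) drop(xmat %*% fit$psi[fit$covariates]) else 0
  names(Lambda) <- as.character(patients)
  structure(list(tau = tau, Lambda = Lambda, x = xmat, groups = cg,
                 psi = fit$psi, spec = spec),
            class = "eb_pred")
}

#' Per-patient treatment-effect trajectory
#'
#' Evaluates `beta_w(t)`, the patient-specific polynomial treatment effect:
#' the fixed time polynomial plus the patient's random slope contributions.
#' The random intercept belongs to `Lambda_w`, not to `beta_w(t)`.
#'
#' @param eb an [eb_pred] object.
#' @param t treatment time (scalar).
#' @return named vector of `beta_w(t)`, one element per patient.
#' @export
treatment_effect <- function(eb, t) {
  stopifnot(inherits(eb, "eb_pred"), length(t) == 1, t >= 0)
  spec <- eb$spec
  beta <- 0
  for (k in seq_len(spec$degree)) beta <- beta + eb$psi[[time_col(k)]] * t^k
  beta <- rep(beta, nrow(eb$tau))
  for (k in setdiff(spec$random_degrees, 0))
    beta <- beta + eb$tau[, time_col(k)] * t^k
  names(beta) <- rownames(eb$tau)
  beta
}

#' Conditional residuals
#'
#' `observed - (fixed part + Z_w tau_w)`; useful for externally checking the
#' normality of the error term with an ordinary QQ plot.
#'
#' @inheritParams predict_random_effects
#' @param eb the [eb_pred] for `fit` on `data`.
#' @return data frame `patient_id`, `time`, `phase`, `residual`.
#' @export
conditional_residuals <- function(fit, eb, data) {
  stopifnot(inherits(eb, "eb_pred"))
  X <- fixed_design(data, fit$spec)
  Z <- random_design(data$time, fit$spec)
  ranpart <- rowSums(Z * eb$tau[match(data$patient_id, rownames(eb$tau)), , drop = FALSE])
  data.frame(patient_id = data$patient_id, time = data$time, phase = data$phase,
             residual = data$response - drop(X %*% fit$psi) - ranpart)
}
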