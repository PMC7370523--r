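#' Disease severity and individual treatment benefit
#'
#' Severity is the probability of missing the therapeutic target `Y <= y`.
#' Before treatment a patient with pre-treatment level `Lambda` has basal
#' severity `s0 = 1 - pnorm((y - Lambda)/sigma_eps)`; after `t` time units of
#' treatment with effect `beta_t` the severity is
#' `s2 = 1 - pnorm((y - Lambda - beta_t)/sigma_eps)`.  The individual benefit
#' is the severity reduction `b = s0 - s2`; for severely ill patients
#' (`s0` near 1) it is well approximated by the closed form
#' `b ~= pnorm((y - Lambda - beta_t)/sigma_eps)`.
#'
#' @param Lambda pre-treatment patient level(s).
#' @param beta_t treatment effect(s) at the time of interest.
#' @param sigma_eps error standard deviation (> 0).
#' @param y therapeutic target threshold.
#' @return severities/benefits, vectorized over `Lambda`/`beta_t`.
#' @export
basal_severity <- function(Lambda, sigma_eps, y) {
  if (any(sigma_eps <= 0)) stop("'sigma_eps' must be positive")
  1 - stats::pnorm((y - Lambda) / sigma_eps)
}

#' @rdname basal_severity
#' @export
treated_severity <- function(Lambda, beta_t, sigma_eps, y) {
  basal_severity(Lambda + beta_t, sigma_eps, y)
}

#' @rdname basal_severity
#' @param s0,s2 basal and on-treatment severities.
#' @export
benefit_exact <- function(s0, s2) s0 - s2

#' @rdname basal_severity
#' @param warn_threshold warn when a basal severity falls below this value
#'   (the severely-ill approximation degrades); set to 0 to silence.
#' @export
benefit_severe <- function(Lambda, beta_t, sigma_eps, y, warn_threshold = 0.9) {
  if (any(sigma_eps <= 0)) stop("'sigma_eps' must be positive")
  s0 <- basal_severity(Lambda, sigma_eps, y)
  low <- s0 < warn_threshold
  if (any(low))
    warning(sum(low), " patient(s) have basal severity < ", warn_threshold,
            "; the severe-illness benefit approximation may be inaccurate")
  stats::pnorm((y - Lambda - beta_t) / sigma_eps)
}

clip_unit <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' EB-predicted individual benefits of a patient sample
#'
#' Plugs the estimated error SD, the EB-predicted `Lambda_w` and treatment
#' effects `beta_w(t)` into the severe-illness benefit formula, and groups
#' patients by their distinct binary covariate pattern.  Benefits are clipped
#' to `[1e-12, 1 - 1e-12]` so that downstream probit transforms stay finite.
#'
#' @param fit a [relm_fit].
#' @param eb the matching [eb_pred].
#' @param y therapeutic target.
#' @param t treatment time at which benefits are evaluated (default: maximum
#'   time used in the fit).
#' @param drop_singletons singleton covariate groups (`N_g = 1`) make the
#'   group-wise diagnostics inapplicable; by default they raise an error,
#'   with `TRUE` they are dropped with a warning.
#' @param warn_threshold see [benefit_severe()].
#' @return object of class `benefit_sample`: data frame `patient_id`, `group`,
#'   `label`, `basal_severity`, `benefit`, `time`, plus covariate columns,
#'   with attributes `t`, `y`, `group_sizes`.
#' @export
eb_benefits <- function(fit, eb, y, t = fit$max_time, drop_singletons = FALSE,
                        warn_threshold = 0.9) {
  stopifnot(inherits(fit, "relm_fit"), inherits(eb, "eb_pred"),
            is.finite(y), t >= 0)
  beta <- treatment_effect(eb, t)
  sig <- sqrt(fit$sigma2_eps)
  b <- clip_unit(benefit_severe(eb$Lambda, beta, sig, y, warn_threshold))
  s0 <- basal_severity(eb$Lambda, sig, y)
  out <- cbind(eb$groups[, c("patient_id", "group", "label")],
               data.frame(basal_severity = s0, benefit = b, time = t,
                          row.names = NULL))
  if (length(fit$covariates))
    out <- cbind(out, eb$groups[, fit$covariates, drop = FALSE])
  sizes <- table(out$group)
  if (any(sizes == 1)) {
    if (!drop_singletons)
      stop("covariate group(s) with a single patient: the group-wise benefit ",
           "diagnostics are not applicable when N_g = 1 ",
           "(use drop_singletons = TRUE to exclude them)")
    keep <- out$group %in% names(sizes)[sizes > 1]
    warning("dropping ", sum(!keep), " patient(s) in singleton covariate group(s)")
    out <- out[keep, , drop = FALSE]
    out$group <- match(out$label, sort(unique(out$label)))
    sizes <- table(out$group)
  }
  rownames(out) <- NULL
  structure(out, t = t, y = y, group_sizes = as.integer(sizes),
            class = c("benefit_sample", "data.frame"))
}

#' Export a benefit sample to CSV
#'
#' Columns `patient_id,group,basal_severity,benefit,time`.
#' @param sample a `benefit_sample`.
#' @param path output path.
#' @export
write_benefits <- function(sample, path) {
  utils::write.csv(as.data.frame(sample)[, c("patient_id", "group",
                                             "basal_severity", "benefit", "time")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
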