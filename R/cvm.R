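#' Cramer-von Mises discrepancy of a benefit sample
#'
#' Quantifies how far the empirical distribution of EB-predicted benefits in
#' one covariate group sits from the theoretical benefit law under normality.
#' With `U_(k) = F(b_(k))` the probability transforms of the sorted benefits,
#' the closed form is
#' `Omega = 1/(12 N_g^2) + (1/N_g) * sum_k (U_(k) - (2k-1)/(2 N_g))^2`,
#' the exact value of `integral (F_N - F)^2 dF`.  Its minimum, attained when
#' the `U_(k)` hit the plotting positions exactly, is `1/(12 N_g^2)`.
#'
#' @param benefits benefit values in (0, 1) for one group (sorted internally).
#' @param law the group's [benefit_law].
#' @return non-negative discrepancy.
#' @export
cvm_group <- function(benefits, law) {
  n <- length(benefits)
  if (n < 1) stop("empty benefit vector")
  if (any(benefits <= 0 | benefits >= 1)) stop("benefits must lie in (0, 1)")
  u <- clip_unit(benefit_cdf(sort(benefits), law))
  k <- seq_len(n)
  1 / (12 * n^2) + sum((u - (2 * k - 1) / (2 * n))^2) / n
}

#' Weighted overall discrepancy
#'
#' `Omega_bar = sum_g N_g Omega_g / N`: the group discrepancies weighted by
#' group size.
#'
#' @param omega per-group discrepancies.
#' @param n_g group sizes.
#' @return weighted mean.
#' @export
cvm_overall <- function(omega, n_g) {
  stopifnot(length(omega) >= 1, length(omega) == length(n_g), all(n_g >= 1))
  sum(n_g * omega) / sum(n_g)
}

#' Overall CVM discrepancy of an EB benefit sample
#'
#' Builds each covariate group's plug-in benefit law from the fit and returns
#' the per-group and size-weighted overall discrepancies.
#'
#' @param sample a `benefit_sample` (see [eb_benefits()]).
#' @param fit the [relm_fit] it came from.
#' @return object of class `cvm_result`: list with `omega` (named per-group),
#'   `n_g`, `omega_bar`.
#' @export
cvm_sample <- function(sample, fit) {
  stopifnot(inherits(sample, "benefit_sample"), inherits(fit, "relm_fit"))
  t <- attr(sample, "t"); y <- attr(sample, "y")
  groups <- sort(unique(sample$group))
  omega <- numeric(length(groups)); n_g <- integer(length(groups))
  for (i in seq_along(groups)) {
    sel <- sample$group == groups[i]
    x <- as.numeric(as.data.frame(sample)[which(sel)[1], fit$covariates])
    law <- benefit_law(fit, x, t, y)
    omega[i] <- cvm_group(sample$benefit[sel], law)
    n_g[i] <- sum(sel)
  }
  names(omega) <- names(n_g) <- sample$label[match(groups, sample$group)]
  structure(list(omega = omega, n_g = n_g,
                 omega_bar = cvm_overall(omega, n_g)),
            class = "cvm_result")
}

#' Sensitivity ratio of replicate-averaged discrepancies
#'
#' `R = mean(Omega_bar, non-normal arm) / mean(Omega_bar, normal arm)`.
#' Values above 1 mean the diagnostic separates the non-normal law from its
#' moment-matched reference normal.
#'
#' @param omegabar_nonnormal,omegabar_normal per-replicate overall
#'   discrepancies for the two arms.
#' @return the ratio `R`.
#' @export
discrepancy_ratio <- function(omegabar_nonnormal, omegabar_normal) {
  stopifnot(length(omegabar_nonnormal) >= 1, length(omegabar_normal) >= 1)
  denom <- mean(omegabar_normal)
  if (denom == 0) stop("zero mean discrepancy in the normal arm")
  mean(omegabar_nonnormal) / denom
}

#' Representative replicate
#'
#' Index of the replicate whose overall discrepancy is closest to the
#' replicate average (ties broken toward the lowest index) — the replicate
#' whose BQQ plot is displayed as typical for the cell.
#'
#' @param omegabars per-replicate overall discrepancies.
#' @return integer index.
#' @export
representative_replicate <- function(omegabars) {
  stopifnot(length(omegabars) >= 1)
  d <- abs(omegabars - mean(omegabars))
  # tolerance guards against ties broken by floating-point rounding
  which(d - min(d) <= 1e-12 * max(1, d))[1]
}
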