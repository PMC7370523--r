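#' Theoretical benefit distribution under random-effect normality
#'
#' When the random effects are jointly normal and patients are severely ill,
#' the individual benefit at time `t` for covariate pattern `x` has CDF
#' `F(z) = pnorm((qnorm(z) - mu)/gamma)` on (0, 1), where
#' `mu = (y - E[Lambda* + beta*(t)]) / sigma_eps` and
#' `gamma^2 = Var(Lambda* + beta*(t)) / sigma_eps^2`.
#' `benefit_law()` computes the plug-in `(mu_hat, gamma_hat)` from a fitted
#' model: `mu_hat` uses the full fixed-effect polynomial and `gamma_hat^2`
#' the quadratic form `z' Sigma_hat z / sigma2_eps` with
#' `z = (t^deg)_{deg in random_degrees}` — which reduces to
#' `(S11 + t^2 S22 + 2 t S12)/sigma2` for a random intercept + linear slope
#' and to the six-term quartic expression when the quadratic slope is random
#' too.
#'
#' @param fit a [relm_fit].
#' @param x covariate pattern: numeric vector of 0/1, one per model covariate
#'   (in the model's covariate order).
#' @param t treatment time.
#' @param y therapeutic target.
#' @return object of class `benefit_law`: list with `mu`, `gamma`, `x`, `t`,
#'   `y`.
#' @export
benefit_law <- function(fit, x, t, y) {
  stopifnot(inherits(fit, "relm_fit"), t >= 0, is.finite(y))
  cv <- fit$covariates
  if (length(x) != length(cv))
    stop("'x' must have one entry per model covariate (", length(cv), ")")
  spec <- fit$spec
  mean_resp <- fit$psi[[1]] +
    (if (length(cv)) sum(fit$psi[cv] * x) else 0) +
    sum(vapply(seq_len(spec$degree),
               function(k) fit$psi[[time_col(k)]] * t^k, 0))
  sig <- sqrt(fit$sigma2_eps)
  z <- t^spec$random_degrees
  z[spec$random_degrees == 0] <- 1
  gamma2 <- drop(z %*% fit$Sigma %*% z) / fit$sigma2_eps
  if (gamma2 <= 0)
    stop("gamma^2 <= 0 (degenerate random-effect covariance): the benefit ",
         "distribution under normality is undefined")
  structure(list(mu = (y - mean_resp) / sig, gamma = sqrt(gamma2),
                 x = x, t = t, y = y),
            class = "benefit_law")
}

#' CDF and quantile function of the benefit distribution
#'
#' `benefit_cdf(z)` evaluates `F(z) = pnorm((qnorm(z) - mu)/gamma)`;
#' `benefit_quantile(p)` its exact inverse `B(p) = pnorm(gamma*qnorm(p) + mu)`.
#'
#' @param z benefit values in (0, 1).
#' @param p probabilities in (0, 1).
#' @param law a [benefit_law] (or any list with `mu` and `gamma`).
#' @return values in (0, 1).
#' @export
benefit_cdf <- function(z, law) {
  if (any(z <= 0 | z >= 1)) stop("'z' must lie strictly in (0, 1)")
  stats::pnorm((stats::qnorm(z) - law$mu) / law$gamma)
}

#' @rdname benefit_cdf
#' @export
benefit_quantile <- function(p, law) {
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  stats::pnorm(law$gamma * stats::qnorm(p) + law$mu)
}

#' Marginal (covariate-averaged) benefit distribution
#'
#' Treats the covariate pattern as random with the empirical group weights:
#' `F_m(z) = sum_g (N_g/N) F(z; x_g, t)`.  The marginal quantile is obtained
#' by bisection on `[1e-12, 1 - 1e-12]` to absolute tolerance `1e-10`
#' (the mixture CDF is strictly increasing, so the bracket is guaranteed).
#'
#' @param z,p evaluation points in (0, 1).
#' @param laws list of [benefit_law] objects, one per covariate group.
#' @param weights group sizes `N_g` (or any positive weights); normalized
#'   internally.
#' @return CDF values / quantiles in (0, 1).
#' @export
marginal_benefit_cdf <- function(z, laws, weights) {
  stopifnot(length(laws) >= 1, length(weights) == length(laws), all(weights > 0))
  w <- weights / sum(weights)
  out <- 0
  for (g in seq_along(laws)) out <- out + w[g] * benefit_cdf(z, laws[[g]])
  out
}

#' @rdname marginal_benefit_cdf
#' @export
marginal_benefit_quantile <- function(p, laws, weights) {
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  vapply(p, function(pp) {
    lo <- 1e-12; hi <- 1 - 1e-12
    flo <- marginal_benefit_cdf(lo, laws, weights) - pp
    fhi <- marginal_benefit_cdf(hi, laws, weights) - pp
    if (flo > 0 || fhi < 0) stop("quantile bracket failure (degenerate law?)")
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (marginal_benefit_cdf(mid, laws, weights) < pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0)
}

#' Benefit percentile curves over treatment time
#'
#' Tabulates `B(p; x, t)` over a time grid for a set of percentiles — the
#' theoretical analogue of plotting per-patient benefit trajectories.
#'
#' @param fit a [relm_fit].
#' @param x covariate pattern.
#' @param y therapeutic target.
#' @param times numeric vector of treatment times.
#' @param probs percentile levels in (0, 1).
#' @return data frame `time`, `p`, `quantile`.
#' @export
percentile_curves <- function(fit, x, y, times,
                              probs = c(0.1, 0.25, 0.5, 0.6, 0.7, 0.75,
                                        0.8, 0.85, 0.9, 0.95)) {
  out <- expand.grid(time = times, p = probs, KEEP.OUT.ATTRS = FALSE)
  out$quantile <- NA_real_
  for (tt in unique(out$time)) {
    law <- benefit_law(fit, x, tt, y)
    sel <- out$time == tt
    out$quantile[sel] <- benefit_quantile(out$p[sel], law)
  }
  out[order(out$p, out$time), , drop = FALSE]
}
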