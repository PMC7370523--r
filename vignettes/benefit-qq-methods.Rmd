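---
title: "Measuring individual treatment benefits and checking the normality assumption with BQQ plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual treatment benefits and checking the normality assumption with BQQ plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benefitqq)
```

## The model

`benefitqq` works with longitudinal trials of a continuous disease score
measured on each patient before treatment ($k_0 \ge 1$ baseline visits at
time 0) and during treatment ($k_1 \ge 1$ visits at times $t > 0$, in
weeks). The response of patient $\omega$ follows a random-effects linear
model: before treatment $Y = \Lambda_\omega + \varepsilon$, and after $t$
weeks of treatment $Y = \Lambda_\omega + \beta_\omega(t) + \varepsilon$,
with

* $\Lambda_\omega = \psi_0 + \tau_{0,\omega} + \boldsymbol\psi_x^T
  \mathbf{x}_\omega$ — the patient's stable pre-treatment level, combining a
  random intercept with fixed effects of binary patient-level covariates;
* $\beta_\omega(t)$ — a degree-$d$ polynomial treatment-effect curve whose
  coefficients may carry random effects (always the intercept; optionally
  the linear and higher slopes, chosen via `relm_spec(degree,
  random_degrees)`);
* $\varepsilon \sim N(0, \sigma_\varepsilon^2)$, homoscedastic and
  independent. We deliberately use a single error variance for the baseline
  and treatment phases; this is usually clinically reasonable, and
  heteroscedastic phases are out of scope.
* random effects $\boldsymbol\tau_\omega$ with mean zero and an
  *unstructured* covariance matrix $\Sigma$, conventionally assumed jointly
  normal. That normality assumption is exactly what the package's
  diagnostics probe.

Estimation is delegated to `lme4::lmer` behind `fit_relm()`, with REML as
the default and ML selectable. REML is the conventional default for variance
components in this model class; all downstream plug-in quantities accept
either, and the package's own checks pass under both. lme4 optimizes the
profiled deviance over a Cholesky-type parameterization of $\Sigma$, which
keeps the estimate positive semi-definite; boundary (singular) estimates are
allowed and flagged on the fit object rather than treated as errors. We use
lme4's own convergence tolerances; `converged` reports whether the optimizer
completed with finite estimates, and any gradient-check messages are kept in
`fit$messages` for inspection.

Time enters as raw polynomial columns $t, t^2, \dots$ without
orthogonalization, matching the clinical parameterization in which
$\psi_2, \psi_3$ are directly interpretable; for long time ranges and high
degrees this is ill-conditioned, and the rank check in `fit_relm()` will
name the offending columns.

## Severity, benefit, and the severely-ill approximation

Given a clinician's target "achieve $Y \le y$", severity is the probability
of missing the target: basal $s_0 = 1 - \Phi((y - \Lambda)/\sigma_\varepsilon)$
and on-treatment $s_2(t)$ with $\Lambda + \beta(t)$ in place of $\Lambda$.
The individual benefit is $b(t) = s_0 - s_2(t)$. When the patient is
severely ill ($s_0 \approx 1$),

$$ b(t) \approx \Phi\!\left(\frac{y - \Lambda - \beta(t)}{\sigma_\varepsilon}\right), $$

with approximation error bounded by $1 - s_0$ (asserted numerically in the
test suite across a parameter grid). `eb_benefits()` warns per patient when
$s_0 < 0.9$ (configurable), and proceeds: trials can mix severely and less
severely ill patients, and the caller should judge whether the
approximation-based diagnostics are meaningful for their sample. Benefits
are clipped to $[10^{-12}, 1 - 10^{-12}]$ before any probit transform so the
tails cannot underflow to exactly 0 or 1.

## The benefit distribution under normality and the BQQ plot

If the random effects are jointly normal then, for severely ill patients
with covariate pattern $\mathbf{x}$ at time $t$, the benefit CDF and
quantile function have closed forms

$$ F(z) = \Phi\!\left(\frac{\Phi^{-1}(z) - \mu}{\gamma}\right), \qquad
   B(p) = \Phi\!\left(\gamma \Phi^{-1}(p) + \mu\right), $$

with $\mu = (y - E[\Lambda^* + \beta^*(t)])/\sigma_\varepsilon$ and
$\gamma^2 = \mathrm{Var}(\Lambda^* + \beta^*(t))/\sigma_\varepsilon^2$.
`benefit_law()` computes the plug-in estimates: $\hat\mu$ from the full
fixed-effect polynomial, and $\hat\gamma^2 = \mathbf{z}^T \hat\Sigma
\mathbf{z} / \hat\sigma_\varepsilon^2$ where $\mathbf{z}$ collects the
powers of $t$ attached to the random terms. The quadratic form reduces
exactly to $(\hat\Sigma_{11} + t^2\hat\Sigma_{22} +
2t\hat\Sigma_{12})/\hat\sigma^2_\varepsilon$ for a random intercept + linear
slope, and to the corresponding six-term quartic expression when the
quadratic slope is random too (verified against both formulas on 1000
random draws in the tests). A degenerate $\hat\Sigma = 0$ makes
$\gamma = 0$ and the law undefined; this errors rather than returning a
point mass.

On the other side sit the **empirical Bayes** predictions. The BLUP
$\hat{\boldsymbol\tau}_\omega = \hat\Sigma Z_\omega^T \hat V_\omega^{-1}
(\mathbf{y}_\omega - X_\omega \hat{\boldsymbol\psi})$, with $\hat V_\omega =
Z_\omega \hat\Sigma Z_\omega^T + \hat\sigma^2_\varepsilon I$, is computed
per patient via linear solves (never explicit inverses) in
`predict_random_effects()`. BLUPs are optimal linear predictors *without*
the normality assumption, so the EB-predicted benefits are robust sample
quantities, while the plug-in quantiles $B(p)$ are valid *only* under
normality — which is what makes their comparison a diagnostic.

A **BQQ plot** (`build_bqq()`) pairs, within each covariate group $g$, the
$i$-th sorted EB benefit with $\hat B((i - 0.5)/N_g;\, \mathbf{x}_g, t)$. By
default $t$ is the maximum treatment time in the dataset, where treatment
effects (and the diagnostic's leverage) are largest; any $t$ can be given.
Groups with a single patient are rejected by default — one order statistic
cannot be compared to a distribution — with an explicit `drop_singletons`
escape hatch. Ties among benefits are kept in stable patient-id order; the
plotting positions are unaffected.

The lineup display (`bqq_lineup()`) simulates `K` datasets from the fitted
null model — normal random effects $N(0, \hat\Sigma)$, errors
$N(0, \hat\sigma^2_\varepsilon)$, at the *observed* design (same visit
times and covariate group sizes) — and refits the model to each replicate
before recomputing its BQQ panel. Refitting, rather than reusing the
original fit, reproduces the estimation noise a null plot genuinely carries.
The observed visit design is reused verbatim for the simulated patients;
this is the closest reading of matched-size null simulation when the design
itself is not being modelled. No formal lineup p-value is computed; the
grid is a visual tool.

## Cramér–von Mises quantification

For group $g$, with $U_{(k)} = \hat F(\hat b_{(k)})$,

$$ \Omega_g = \frac{1}{12 N_g^2} + \frac{1}{N_g} \sum_{k=1}^{N_g}
   \left(U_{(k)} - \frac{2k - 1}{2 N_g}\right)^2 $$

is the exact value of $\int (F_{N_g} - F)^2 \, dF$ (checked against a
$10^6$-point numerical integral in the tests), with minimum
$1/(12 N_g^2)$ at a perfect fit. The overall discrepancy is the
size-weighted mean $\bar\Omega = \sum_g N_g \Omega_g / N$. $U$ values are
clipped away from 0 and 1 before squaring to guard against tail underflow.

## The simulation study

`scenario_config()` / `run_scenario()` implement a four-scenario experiment
in which data are generated from a known non-normal random-effects law and,
in a parallel arm, from the **reference normal** distribution with the same
mean and covariance (`reference_normal()`): an equal-weight symmetric
bivariate normal mixture with separation $2w$ (scenario 1), an asymmetric
$(3/4, 1/4)$ mixture (scenario 2), a trivariate t with $v$ degrees of
freedom — built as $m + Z\sqrt{v/\chi^2_v}$ so its covariance is
$\frac{v}{v-2}\Gamma$ (scenario 3) — and a symmetric trivariate mixture with
separation $w\sqrt 8$ (scenario 4). Moment matching between the two arms is
the study's central construct and is verified by simulation in the test
suite. The fixed effects, error variance 10, Bernoulli(0.6) covariate,
target $y = 7$, evaluation time $t = 4$ and the visit grids (0,0,1,4 or
0,0,1,2,3,4) are fixed study conditions chosen so that essentially all
simulated patients are severely ill ($P(s_0 > 0.9) \ge 0.95$, checked by
Monte Carlo).

Each replicate simulates a dataset, fits the scenario's model by REML,
EB-predicts benefits at $t = 4$, and records $\bar\Omega$; the sensitivity
ratio $R$ compares the replicate means of the two arms. Replicates whose
fit fails outright (optimizer error, non-finite estimates, or a degenerate
benefit law) are resimulated from a fresh child seed and counted;
gradient-check warnings with finite estimates are not treated as failures.
Seeding is hierarchical: the master seed draws one child seed per
replicate-arm up front, and retry $a$ of a child seed $s$ uses
$(s + 1000003\,a) \bmod (2^{31} - 1)$, so the two arms are independent
streams and any replicate can be reconstructed in isolation
(`replicate_details()`).

Default problem sizes in the examples and checks are $N = 100$ patients,
$n = 6$ visits and 100 replicates per arm — enough that the ratio $R$
separates cleanly from 1 in the non-normal scenarios while a full cell runs
on a desktop in well under a minute; the full grids over
$N \in \{30, \dots, 500\}$ and all scenario parameters are available by
looping `run_scenario()` over configurations.

## What the generator does and does not emulate

The synthetic datasets reproduce the structure of a depression-trial
application: two baseline visits, up to four weekly on-treatment visits,
one binary patient-level covariate, polynomial time trends with unstructured
random-effect covariance, homoscedastic Gaussian errors, and no missing
visits. Real trials additionally feature dropout and intermittent
missingness, measurement floors/ceilings (rating scales are bounded),
serially correlated within-patient errors, and continuous covariates —
none of which the generator produces. Passing checks therefore demonstrate
the correctness and sensitivity of the machinery under the stated model,
not robustness to those real-data complications; the diagnostics themselves
remain applicable to real data so long as the fitted model class matches.

## Numerical choices and limitations

* Marginal-quantile inversion (`marginal_benefit_quantile`) uses bisection
  on $[10^{-12}, 1 - 10^{-12}]$ to tolerance $10^{-10}$; the mixture CDF is
  strictly monotone so the bracket always holds. Single-group marginals
  reduce exactly to the closed-form quantile.
* Quantiles at plotting positions always use the closed form, never
  interpolation.
* Probit round-trips are exact to $10^{-10}$ for laws whose quantiles stay
  away from the representable edge of $(0, 1)$; for extreme $\mu, \gamma$
  the double-precision representation of values near 1 caps the achievable
  accuracy.
* The diagnostic needs $N_g$ large enough for sample quantiles to be
  informative; it is inapplicable at $N_g = 1$ and weak for very small
  groups. Continuous covariates must be categorized before use. The
  benefit formulas assume severely ill patients; no closed form exists
  otherwise, and extending the plot to that case would require numerical or
  Monte-Carlo integration.
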