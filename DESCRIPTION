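Package: benefitqq
Title: Benefit Quantile-Quantile Diagnostics for Individual Treatment
    Benefit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures individual treatment benefits of severely ill patients
    from random-effects linear models of longitudinal continuous outcomes, and
    assesses the goodness-of-fit of the normality assumption for the random
    effects with benefit quantile-quantile (BQQ) plots.  Provides empirical
    Bayes (BLUP) prediction of per-patient benefits, the closed-form benefit
    distribution under normality, Cramer-von Mises discrepancy summaries,
    lineup plots against null simulations, and a four-scenario simulation
    study comparing non-normal random-effect laws with moment-matched
    reference normal distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    MASS,
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
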