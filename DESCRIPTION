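Package: gppanel
Title: Bayesian Gamma-Poisson Panel Models with Mundlak and Fixed-Effects Intercepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits overdispersed (Gamma-Poisson, i.e. negative binomial) count
    regressions to balanced state-year panels with a log-population offset,
    using either partially pooled random intercepts augmented with the group
    mean of the exposure (the Mundlak device) or per-group fixed effects.
    Includes a seedable adaptive Metropolis sampler, split R-hat and
    effective-sample-size convergence diagnostics, highest posterior density
    intervals, incidence-rate-ratio reporting, posterior predictive
    simulation, and a causally structured synthetic panel generator for
    parameter-recovery studies of exposure effects on mortality counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    ggplot2,
    rjags,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
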