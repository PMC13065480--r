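Package: alepanel
Title: Non-Random Patterns in Adverse Life Event Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how adverse life events (illness, bereavement,
    job loss, accidents) cluster and accumulate in longitudinal household
    panels. Provides a long-format person-year data model with event catalogs
    and mutual-exclusivity groups; synthetic panel generators for three
    accumulation regimes (homogeneous Poisson, crossed individual/household
    frailty, and self-reinforcing Polya urn) plus a cross-event dependence
    generator; a maximum-likelihood engine for Poisson, binomial, and
    beta-binomial regression with crossed random intercepts via the Laplace
    approximation, including profile confidence intervals and latent-scale
    variance decomposition; contemporaneous and lag-1 odds-ratio analyses;
    an accumulation model comparison (AIC/BIC) with forward simulation; and
    heavy-tail characterization of cumulative counts with KS-estimated lower
    thresholds and Vuong's non-nested likelihood-ratio test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    tibble,
    utils,
    yaml
Suggests:
    glmmTMB,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
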