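---
title: "Modelling co-occurrence and accumulation of adverse life events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-occurrence and accumulation of adverse life events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alepanel)
```

## The scientific question

Adverse life events (ALEs) — illness, bereavement, job loss, accidents —
are recorded in household panel studies as yearly binary indicators per
person. If adversity were pure "bad luck", events would be independent
across people, event types, and years, and twenty-year cumulative counts
would look Poisson. Real panels instead show events clustering within
person-years, predicting next year's events, and accumulating into heavy
right tails. `alepanel` implements the full analysis chain for asking how
far a panel departs from randomness, and *which* generative mechanism —
homogeneous chance, stable heterogeneous risk (frailty), or
self-reinforcement (a Polya urn) — describes the accumulation best. Since
the national panels this design targets are access-restricted, the package
pairs every analysis with a synthetic generator that produces panels with
the same statistical structure, so the whole chain is testable end to end.

## Data model

A panel is a long table of person-years: individual id, household id,
calendar year, age, and one 0/1/NA column per event in a catalog
(`ale_catalog()`). Catalogs carry two structural facts the models need:

* **Mutual-exclusivity groups.** Some instruments record only one
  personal illness/accident subcategory per year; members of such a group
  can never co-occur. A group of g events therefore contributes a single
  "slot", and the number of independent event slots per person-year is
  `k_trials = n_events - sum(group_size - 1)`. The bundled
  `catalog_swiss()` (12 events, one 7-member group, `k_trials = 6`) and
  `catalog_australia()` (13 unrestricted events, `k_trials = 13`) mirror
  the two instruments this design emulates; their labels are synthetic
  stand-ins.
* **A reference label**, the "other/unspecified" subcategory, which is
  dropped as a predictor in every co-occurrence model (with a full set of
  group indicators it is structurally collinear).

Filters mirror the target studies: person-years under age 18 are removed
(boundary inclusive), person-years with *all* events missing are dropped,
and remaining missing indicators are counted as non-events
(`impute_missing_as_zero()`, with the audit mask retained so the
imputation rate stays reportable). "Consecutively observed" means calendar
years increasing in steps of exactly 1; when an individual has several
qualifying runs, the earliest is kept — the choice is arbitrary but
deterministic, which we value more here.

## The three accumulation processes

For yearly counts \(Y_{it}\) (0 to `k_trials` events):

* **Bad luck (Poisson).** \(Y_{it} \sim \text{Pois}(\lambda)\), one rate
  for everyone. Variance equals the mean; no clustering beyond chance.
* **Frailty.** \(Y_{it} \mid u_i, v_h \sim
  \text{Pois}(\lambda e^{u_i + v_h})\) with crossed log-normal random
  intercepts for individual and household. Risk differs across entities
  but is static in time; counts are conditionally independent.
* **Polya urn.** Each person owns an urn with `w` white (no-event) and
  `b` blue (event) balls; each of `k` yearly draws is returned with `c`
  extra balls of its colour, so events raise their own future
  probability. By exchangeability the cumulative total after `m` draws is
  exactly BetaBinomial(`m`, `b/c`, `w/c`); the package tests this law
  directly against the literal urn simulator. The estimable surrogate is
  a beta-binomial mixed model for yearly counts out of `k_trials`, in the
  Morris parameterization \(\mu = \alpha/(\alpha+\beta)\),
  \(\phi = \alpha+\beta\), variance
  \(\mu(1-\mu)\,n(\phi+n)/(\phi+1)\), with the same crossed intercepts.

The models are compared by AIC and BIC on identical data
(`compare_accumulation()`), reported as `delta = fit(left) - fit(right)`
for (Poisson, Frailty) and (Frailty, Polya), so positive numbers favour
the richer process. `fit_polya()` takes `k_trials` from the catalog,
never from data maxima: an observed count above the bound is a data
error, not a reason to stretch the model.

One approximation deserves emphasis: the fitted "urn" model treats yearly
counts as conditionally beta-binomial given the entity effects, i.e. it
ignores the serial dependence the literal urn induces *within* an entity's
draw sequence. On urn-generated data the mixed-model likelihood can
therefore place the self-reinforcement either in the dispersion
\(\phi\) (year-to-year overdispersion) or in the random intercepts
(persistent heterogeneity with \(\phi \to \infty\)); these are two genuine
local optima. `fit_glmm()` starts from both regimes by default
(`multistart`); whichever mode wins, the *model-selection* conclusion is
unaffected, because both lie far above the frailty and Poisson fits.

## The mixed-model engine

All regressions — binomial-logit co-occurrence models, the Poisson
autocorrelation model, and the accumulation fits — share one
maximum-likelihood engine for crossed random intercepts
(`fit_glmm()`). Crossed designs defeat per-group adaptive quadrature, so
the marginal likelihood uses the Laplace approximation: a damped Newton
solver finds the joint mode over the stacked random-effect vector, and
the Gaussian correction uses the log-determinant of the sparse negative
Hessian (sparse Cholesky via the Matrix package, with the symbolic
factorization reused across iterations). Correctness is anchored two
ways: on fixtures with up to six random-effect levels the Laplace value
must sit within 0.1 of a dense tensor adaptive Gauss–Hermite quadrature
over the entire random-effect vector (`marginal_loglik_quadrature()`,
whose mode search and dense algebra are deliberately independent of the
production path), and with all SDs at zero it must equal the plain GLM
log-likelihood to machine precision. The test suite additionally
cross-checks full fits against glmmTMB, which estimates the same models
by Laplace approximation through automatic differentiation.

Numerical choices, all adjustable through `glmm_control()`:

* The outer optimizer works on the **SD scale with a lower bound of 0**
  (not log-SD), so no-heterogeneity fits land exactly on the boundary
  instead of crawling down an unbounded log scale; boundary fits are
  reported as `converged_at_boundary`, never as failures. The
  beta-binomial dispersion is optimized as \(\log\phi\) with an upper
  bound (default \(e^{16}\)); hitting it means "no detectable
  overdispersion" (binomial limit) and is flagged.
* Fixed effects are profiled into the inner Newton solve (a Schur
  complement on the sparse factor), so the outer dimension is just the
  variance parameters; a final joint `polish` on the exact Laplace
  objective then refines all parameters. Replicate studies in the test
  suite disable the polish and the multistart and relax `rel_tol` to
  `1e-6`: the quantities they measure (AIC orderings, CI coverage) are
  insensitive at these scales, and the defaults stay conservative for
  single fits.
* Default tolerances: relative objective change `1e-8`, at most 200
  outer iterations, three seeded jittered restarts on non-convergence.
* Wald covariance: for models with up to `full_vcov_max` (default 6)
  total parameters, the full joint observed information of the Laplace
  objective is used (finite differences at step 0.02 — large enough to
  sit well above the inner solver's noise floor), so intercept intervals
  carry the variance-parameter uncertainty; in larger models the
  fixed-effect covariance is conditional on the variance parameters (as
  in lme4) and variance-parameter intervals come from the curvature of
  the profiled objective on the log scale. In an intercept-only Poisson
  mixed model the conditional intercept interval is visibly too narrow
  (the intercept and the SDs are correlated), which is why the joint
  version is the small-model default.
  Profile likelihood intervals (`profile_ci()`) bisect the signed
  likelihood-ratio statistic against \(\chi^2_1\) and are the reference
  method; they are computed on demand because a full odds-ratio matrix
  involves hundreds of cells.
* Any fixed effect beyond 15 on the link scale triggers a
  separation/rare-event warning, and the affected odds-ratio cells are
  reported absent-with-diagnostic rather than with meaninglessly wide
  intervals.

The latent-scale variance decomposition (`variance_decomposition()`)
reports marginal and conditional \(R^2\) and the adjusted ICC. The
residual variance is \(\pi^2/3\) for the logit links and the log-normal
approximation \(\log(1 + 1/\bar\lambda)\) for the Poisson log link, with
\(\bar\lambda\) the marginal mean rate. The Poisson convention is one of
several in circulation, so Poisson decompositions should be compared
across software qualitatively, not digit by digit. Note that applying the
\(\pi^2/3\) convention to the beta-binomial ignores the extra dispersion
mass, which also makes beta-binomial ICCs comparable only within this
package.

## Co-occurrence analyses

`fit_contemporaneous()` fits, per outcome event, a binomial-logit mixed
model with all other events as predictors and crossed random intercepts;
`fit_lag1()` does the same with outcomes lagged one year (the outcome's
own type enters as a predictor, so the diagonal measures within-event
persistence, and the household id is the outcome-year one, since
membership can change). For an outcome inside an exclusivity group the
other members are removed as contemporaneous predictors — given the
outcome they are structurally zero — and those cells are *absent* in the
output, never OR = 0. Lagged group members are retained (last year's
subcategory is not structurally zero this year). The unadjusted
sensitivity variant (`fit_unadjusted()`) fits one predictor at a time on
the same rows; `percent_difference()` is literally
\(100 (\text{OR}_u - \text{OR}_a)/\text{OR}_a\), and `sign_reversals()`
lists the significant adjusted cells whose unadjusted OR sits on the
other side of 1.

No multiple-testing correction is applied — significance means the 95%
interval excludes 1 — deliberately matching the analysis this package
operationalizes; with on the order of \(p^2\) cells per matrix, users
should read lone marginal cells accordingly.

## Tail characterization

Twenty-year cumulative counts are summarized (`count_summaries()`) with
*both* dispersion statistics under unambiguous names (`sd_over_mean`,
`var_over_mean`), because a "coefficient of variation" reported for such
data can be either. Zero totals are excluded (`exclude_zeros()`), then
four models are fitted above a threshold `x_min` chosen by minimizing the
Kolmogorov–Smirnov distance between fitted and empirical tail CDFs, ties
toward the smallest threshold: a discrete power-law (Hurwitz-zeta
normalized), a truncated Poisson, and continuous exponential and
log-normal densities truncated at `x_min` — the dialect of the standard
heavy-tail toolkit, recorded in each fit. `vuong_compare()` re-fits both
models at a common threshold (the mean of the two estimates, rounded down
to an observed value, our deterministic reading of "median of the two"),
and the normalized mean pointwise log-likelihood difference is referred
to a standard normal; identical models give statistic 0 and p = 1 by
convention. KS is used only as a selection objective; no small-sample KS
p-values are attached.

## The synthetic generators

`simulate_poisson_panel()`, `simulate_frailty_panel()`,
`simulate_urn_panel()` generate count panels under the three regimes;
`simulate_typed_panel()` generates binary event panels with planted
contemporaneous and lag-1 log-odds-ratios via sequential conditional
sampling in catalog order (an exclusivity group is sampled as one
categorical slot), plus shared entity intercepts;
`simulate_count_ar_panel()` generates the log-linear lag-autocorrelated
counts the autocorrelation model estimates, truncated at a yearly
maximum both because instruments record finitely many events and because
untruncated positive feedback at a rate ratio of 1.17 diverges.
Defaults and study conditions follow the published design: rates around
0.5–0.96 events/person-year, random-intercept SDs 0.27–0.47, urn
compositions matching the fitted shapes (e.g. alpha 25.57, beta 150.47 at
unit reinforcement), 1,370–3,700 individuals over 20 years, base event
rates spanning roughly 0.1%–15%.

All generators are bit-reproducible given (parameters, seed); one seed
expands into named sub-streams per randomness source. Count-level
generators lay draws out individual-major, so panels differing only in
size share the draws of their common individuals; the typed generator
vectorizes across individuals within each year and is reproducible but
not prefix-stable, a documented trade-off for speed. What the generators
deliberately do not emulate: attrition mechanisms, interview-mode
effects, demographic composition beyond a uniform adult age draw, and
within-year event timing. Passing tests on synthetic panels therefore
demonstrate that the *estimators* recover the structure they assume —
they do not validate those assumptions on real survey data.

## Problem sizes and what the tests check

The test suite exercises the chain at deliberately chosen scales: exact
identities and quadrature fixtures at a handful of observations;
recovery and calibration studies at 300–2,500 individuals over 10–20
years (frailty CI coverage across 100 replicates; a 132-cell odds-ratio
type-I calibration pooled over four independence panels of 50,000
person-years; planted OR = 2 recovery); model selection at the published
panel scale (1,370 individuals x 20 years, 100 replicates); tail fits at
10,000 counts. The acceptance script (`scripts/acceptance.R`) re-runs a
single-panel version of each and writes the resulting numbers as JSON.

## Known limitations

* Laplace accuracy degrades for binary outcomes with very few
  observations per entity; the quadrature oracle bounds the error only
  at fixture scale.
* Random slopes, sampling weights, GEE/Bayesian estimation, and
  simulation-based residual diagnostics are out of scope.
* The beta-binomial surface's two-regime geometry means reported
  \(\phi\) and SDs from urn-generated data should be read jointly, not
  separately.
* Adjusted odds ratios condition on all other events; with mediators or
  colliders among them, estimates are descriptive associations, not
  causal effects.
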