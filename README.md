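# alepanel

Tools for studying **non-random patterns in adverse life events (ALEs)**
— illness, bereavement, accidents, job loss — as they are recorded in
longitudinal household panels: one binary indicator per event type per
person-year, with individuals nested (non-exclusively) in households.

The package is aimed at researchers in epidemiology, stress and
life-course studies who want to ask, on panel data of this shape:

* Which events co-occur within a year, and which predict events the
  following year? (odds-ratio matrices from binomial-logit mixed models
  with crossed individual and household random intercepts)
* How strongly do event counts autocorrelate year over year?
  (`count ~ 1 + age + age^2 + lag-1 count + (1|individual) + (1|household)`,
  Poisson)
* Which generative process best describes twenty-year accumulation —
  homogeneous chance, stable heterogeneous risk, or self-reinforcement?

The accumulation comparison is the core. Three processes are fitted to
the same consecutively-observed panel and compared by AIC/BIC:

| model | structure |
|---|---|
| bad luck | `Y ~ Poisson(lambda)`, one rate for everyone |
| frailty | `Y | u,v ~ Poisson(lambda e^{u_i + v_h})`, crossed log-normal intercepts |
| Polya urn | `Y | u,v ~ BetaBinomial(k, mu, phi)`, logit-normal crossed intercepts |

The urn model encodes *adversity begets adversity*: an urn with `w`
white and `b` blue balls, each draw returned with `c` extra balls of its
colour, has exchangeable totals that are exactly
`BetaBinomial(m, b/c, w/c)` after `m` draws — so the fitted shape
parameters map back to an urn via `alpha = b/c`, `beta = w/c`, with mean
`mu = alpha/(alpha+beta)` and dispersion `phi = alpha + beta` (Morris
parameterization, variance `mu(1-mu) n(phi+n)/(phi+1)`).

Because the national panels this design targets are access-restricted,
the package includes first-class synthetic generators for every regime
(plus planted cross-event and lag-1 dependence, missingness, and
household structure), and all regressions run on a purpose-built
maximum-likelihood engine for crossed random intercepts using the
Laplace approximation with sparse Cholesky algebra — validated in the
test suite against dense adaptive Gauss–Hermite quadrature and against
glmmTMB. Heavy-tail characterization of cumulative counts (power-law /
log-normal / exponential / Poisson fits above a KS-estimated threshold,
compared by Vuong's test) rounds out the chain.

## Worked example

Simulate a self-reinforcing panel at the fitted composition of one of
the published studies (`alpha = 25.57`, `beta = 150.47`, six event slots
per year), then ask which accumulation process explains it:

```r
library(alepanel)

us <- urn_spec(white = 150.47, blue = 25.57, reinforcement = 1,
               draws_per_year = 6)
households <- make_household_map(600, 480, seed = 42)
panel <- simulate_urn_panel(us, 600, 20, seed = 42,
                            household_map = households)
panel
#> <ale_panel> 12000 person-years, 600 individuals, 480 households (counts)

cmp <- compare_accumulation(panel, ale_catalog(paste0("event_", 1:6)))
cmp
#> <accumulation_comparison>
#>      left   right delta_aic delta_bic
#> 1 poisson frailty  26.89621  12.11088
#> 2 frailty   polya 154.58336 147.19070
#> preferred by AIC: polya | by BIC: polya
```

Positive deltas say the right-hand model fits better: heterogeneous risk
(frailty) beats uniform bad luck by ~27 AIC, and the self-reinforcing
urn beats frailty by a further ~155 — the correct call, since the panel
*was* urn-generated. The cumulative counts show the overdispersion that
drives this:

```r
count_summaries(panel)$cumulative_stats
#> # A tibble: 1 x 6
#>    mean median   min   max sd_over_mean var_over_mean
#>   <dbl>  <dbl> <int> <int>        <dbl>         <dbl>
#> 1  17.4     17     5    34        0.279          1.36

x <- exclude_zeros(count_summaries(panel)$cumulative$total)
vuong_compare(estimate_xmin(x, "lognormal")$fit,
              estimate_xmin(x, "powerlaw")$fit, x)
#> <vuong_result> lognormal vs powerlaw at xmin = 14 (n = 468): statistic = 12.595, p = 2.258e-36
```

A variance/mean ratio of 1.36 for 20-year totals (a Poisson process
would give 1), and a tail better described by a log-normal than a power
law (positive Vuong statistic favours the first model).

Other entry points: `fit_contemporaneous()` / `fit_lag1()` /
`fit_unadjusted()` for odds-ratio matrices, `fit_autocorrelation()` for
the lagged count model, `fit_glmm()` / `profile_ci()` /
`variance_decomposition()` for the engine itself, `simulate_typed_panel()`
for binary panels with planted dependence, and `run_pipeline()` for a
config-driven end-to-end run with a provenance manifest (a thin CLI
wrapper lives in `inst/exec/ale.R`). The methods vignette
(`vignettes/adverse-life-event-patterns.Rmd`) documents the models,
their assumptions, and every numerical choice.

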