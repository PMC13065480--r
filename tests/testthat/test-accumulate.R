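test_that("the bad-luck model is the sample-mean Poisson fit", {
  pan <- ale_panel(tibble::tibble(id = 1:4, hh_id = 1:4, year = 2001,
                                  count = c(2L, 0L, 1L, 1L)),
                   catalog = NULL, validate = FALSE)
  fit <- fit_bad_luck(pan)
  expect_equal(unname(exp(fit$coefficients)), 1.0, tolerance = 1e-7)
  expect_equal(fit$df, 1)
  expect_equal(fit$AIC, -2 * fit$loglik + 2)
  # large-sample rate recovery at the second study's scale
  pan2 <- simulate_poisson_panel(0.62, 3700, 20, seed = 51)
  fit2 <- fit_bad_luck(pan2)
  expect_lt(abs(exp(fit2$coefficients[[1]]) - 0.62), 0.01)
})

test_that("frailty fits collapse to the boundary on homogeneous data", {
  pan <- simulate_poisson_panel(0.8, 400, 10, seed = 52)
  hh <- make_household_map(400, 160, seed = 52)
  pan$hh_id <- hh$hh_id[match(pan$id, hh$id)]
  ff <- fit_frailty(pan)
  fp <- fit_bad_luck(pan)
  expect_lt(sum(ff$sd), 0.05)
  expect_gte(ff$loglik, fp$loglik - 1e-6) # nesting
})

test_that("the urn model demands counts within the catalog's trial bound", {
  cat6 <- ale_catalog(paste0("e", 1:6))
  pan <- ale_panel(tibble::tibble(id = 1:3, hh_id = 1:3, year = 2001,
                                  count = c(2L, 7L, 1L)),
                   catalog = NULL, validate = FALSE)
  expect_error(fit_polya(pan, cat6), "k_trials = 6")
})

test_that("fit comparisons are exact AIC/BIC arithmetic in the stated orientation", {
  us <- urn_spec(6, 2, 1, 6)
  hh <- make_household_map(250, 100, seed = 53)
  pan <- simulate_urn_panel(us, 250, 10, seed = 53, household_map = hh)
  cmp <- compare_accumulation(pan, ale_catalog(paste0("e", 1:6)),
                              control = glmm_control(polish = FALSE))
  fits <- cmp$fits
  expect_equal(cmp$comparison$delta_aic[1],
               fits$poisson$AIC - fits$frailty$AIC)
  expect_equal(cmp$comparison$delta_aic[2],
               fits$frailty$AIC - fits$polya$AIC)
  expect_equal(cmp$comparison$delta_bic[1],
               fits$poisson$BIC - fits$frailty$BIC)
  # antisymmetry of the delta under swapping the pair
  expect_equal(fits$frailty$AIC - fits$poisson$AIC,
               -cmp$comparison$delta_aic[1])
  # self-reinforcing data prefer the urn model
  expect_equal(cmp$winner_aic, "polya")
})

test_that("forward simulation reproduces the fitted process", {
  pan <- simulate_poisson_panel(0.9, 800, 6, seed = 54)
  fit <- fit_bad_luck(pan)
  sim <- simulate_fitted(fit, ale_catalog(paste0("e", 1:6)), 800, 6,
                         reps = 2, seed = 55)
  expect_identical(sim,
                   simulate_fitted(fit, ale_catalog(paste0("e", 1:6)),
                                   800, 6, reps = 2, seed = 55))
  # year-6 cumulative counts are Poisson(6 * rate): compare mean/variance
  y6 <- sim[sim$year == 6 & sim$rep == 1, ]
  mean6 <- sum(y6$count * y6$n) / sum(y6$n)
  var6 <- sum((y6$count - mean6)^2 * y6$n) / sum(y6$n)
  lam6 <- 6 * exp(fit$coefficients[[1]])
  expect_lt(abs(mean6 - lam6), 0.3)
  expect_lt(abs(var6 / lam6 - 1), 0.15)
  # a fitted frailty process has a heavier cumulative tail than Poisson
  hh <- make_household_map(800, 320, seed = 56)
  panf <- simulate_frailty_panel(frailty_params(0.9, 0.5, 0.4), hh, 6,
                                 seed = 56)
  fitf <- fit_frailty(panf)
  simf <- simulate_fitted(fitf, ale_catalog(paste0("e", 1:6)), 800, 6,
                          reps = 2, seed = 57)
  yf <- simf[simf$year == 6 & simf$rep == 1, ]
  meanf <- sum(yf$count * yf$n) / sum(yf$n)
  varf <- sum((yf$count - meanf)^2 * yf$n) / sum(yf$n)
  expect_gt(varf / meanf, 1.3)
})

test_that("autocorrelation estimates vanish when temporal order is destroyed", {
  hh <- make_household_map(800, 320, seed = 58)
  pan <- simulate_count_ar_panel(0.5, 1.25, 0.25, 0.25, hh, 10, seed = 58)
  fit <- fit_autocorrelation(pan)
  est <- exp(fit$coefficients[["lag_count"]])
  expect_gt(est, 1.1) # dependence present in ordered data
  # permuting each individual's years breaks the lag-1 dependence
  set.seed(59)
  shuf <- pan
  for (i in unique(pan$id)) {
    rows <- which(pan$id == i)
    shuf$count[rows] <- pan$count[sample(rows)]
  }
  fit0 <- fit_autocorrelation(shuf)
  est0 <- glmm_estimates(fit0, natural = TRUE)
  lag0 <- est0[est0$term == "lag_count", ]
  expect_lt(abs(log(lag0$estimate)), 0.05)
  # age standardization constants are stored for reproducibility
  expect_named(fit$age_scaling, c("mean", "sd"))
})
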