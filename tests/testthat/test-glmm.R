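test_that("Laplace marginal likelihood matches dense quadrature on crossed fixtures", {
  df <- tiny_crossed_data()
  spec <- glmm_spec("poisson", response = "y",
                    groups = c("individual", "household"))
  for (par in list(list(beta = 0.1, sd = c(0.4, 0.3)),
                   list(beta = -0.5, sd = c(0.8, 0.2)),
                   list(beta = 0.3, sd = c(0.1, 0.6)))) {
    la <- laplace_loglik(spec, df, par)
    qu <- marginal_loglik_quadrature(spec, df, par, nodes = 15)
    expect_lt(abs(la - qu), 0.1)
  }
  # binomial family too
  df$y <- pmin(df$y, 2)
  specb <- glmm_spec("binomial", response = "y",
                     groups = c("individual", "household"), trials = 2)
  parb <- list(beta = -0.3, sd = c(0.5, 0.4))
  expect_lt(abs(laplace_loglik(specb, df, parb) -
                  marginal_loglik_quadrature(specb, df, parb, nodes = 15)),
            0.1)
})

test_that("zero variance components reduce exactly to the fixed-effect GLM", {
  df <- tiny_crossed_data()
  spec <- glmm_spec("poisson", response = "y",
                    groups = c("individual", "household"))
  la0 <- laplace_loglik(spec, df, list(beta = 0.1, sd = c(0, 0)))
  expect_equal(la0, sum(dpois(df$y, exp(0.1), log = TRUE)), tolerance = 1e-10)
  # one component zero, the other integrated
  la1 <- laplace_loglik(spec, df, list(beta = 0.1, sd = c(0.4, 0)))
  qu1 <- marginal_loglik_quadrature(spec, df,
                                    list(beta = 0.1, sd = c(0.4, 0)),
                                    nodes = 21)
  expect_lt(abs(la1 - qu1), 0.05)
})

test_that("closed-form maximum-likelihood estimates are reproduced", {
  # intercept-only Poisson: the MLE is the sample mean
  fit <- fit_glmm(glmm_spec("poisson", response = "y",
                            groups = character(0)),
                  data.frame(y = c(2, 0, 1, 1)))
  expect_equal(unname(exp(fit$coefficients)), 1.0, tolerance = 1e-7)
  expect_equal(fit$loglik, sum(dpois(c(2, 0, 1, 1), 1, log = TRUE)),
               tolerance = 1e-8)
  expect_equal(fit$AIC, -2 * fit$loglik + 2)
  # 2x2 logistic table: OR = ad/bc = 10*20 / (5*2) = 20
  df <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 5, 2, 20)),
                   x = rep(c(1, 1, 0, 0), c(10, 5, 2, 20)))
  fitb <- fit_glmm(glmm_spec("binomial", response = "y", fixed = "x",
                             groups = character(0), trials = 1), df)
  expect_equal(unname(exp(fitb$coefficients["x"])), 20, tolerance = 1e-4)
})

test_that("likelihood is invariant to covariate scaling and null covariates", {
  set.seed(21)
  hh <- make_household_map(80, 40, seed = 21)
  pan <- simulate_frailty_panel(frailty_params(0.7, 0.3, 0.2), hh, 6,
                                seed = 21)
  df <- data.frame(y = pan$count, individual = pan$id,
                   household = pan$hh_id,
                   x = rnorm(nrow(pan)), z = 0)
  sp <- function(fx) glmm_spec("poisson", response = "y", fixed = fx,
                               groups = c("individual", "household"))
  f1 <- fit_glmm(sp("x"), df)
  df$x10 <- df$x * 10
  f2 <- fit_glmm(sp("x10"), transform(df, x10 = x * 10))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["x"]),
               unname(10 * f2$coefficients["x10"]), tolerance = 1e-3)
  # an all-zero covariate cannot change the maximized likelihood
  f0 <- fit_glmm(sp(character(0)), df)
  fz <- fit_glmm(sp("z"), df)
  expect_equal(f0$loglik, fz$loglik, tolerance = 1e-6)
  # nesting: the mixed model can never fit worse than the plain GLM
  glm0 <- fit_glmm(glmm_spec("poisson", response = "y",
                             groups = character(0)), df)
  expect_gte(f0$loglik, glm0$loglik - 1e-8)
  # information-criterion arithmetic holds exactly
  for (f in list(f0, fz, glm0)) {
    expect_equal(f$AIC, -2 * f$loglik + 2 * f$df)
    expect_equal(f$BIC, -2 * f$loglik + f$df * log(f$n_obs))
  }
})

test_that("the beta-binomial converges to the binomial as phi grows", {
  df <- data.frame(y = c(0, 1, 2, 3, 1, 0), individual = 1:6,
                   household = rep(1:3, 2))
  lb <- laplace_loglik(glmm_spec("binomial", response = "y",
                                 groups = c("individual", "household"),
                                 trials = 4),
                       df, list(beta = -0.4, sd = c(0.3, 0.2)))
  lbb <- laplace_loglik(glmm_spec("betabinomial", response = "y",
                                  groups = c("individual", "household"),
                                  trials = 4),
                        df, list(beta = -0.4, sd = c(0.3, 0.2), phi = 1e6))
  expect_lt(abs(lb - lbb), 1e-3)
})

test_that("boundary and separation cases are flagged, not failed", {
  # homogeneous data: variance components collapse to the sigma = 0 boundary
  pan <- simulate_poisson_panel(0.7, 300, 8, seed = 31)
  hh <- make_household_map(300, 120, seed = 31)
  pan$hh_id <- hh$hh_id[match(pan$id, hh$id)]
  fit <- fit_frailty(pan)
  expect_match(fit$convergence, "converged")
  expect_lt(sum(fit$sd), 0.12)
  # profile lower endpoint for a boundary SD is zero
  ci <- profile_ci(fit, "sd_household")
  expect_equal(unname(ci["lower"]), 0)
  # complete separation in a logistic fit triggers the rare-event warning
  dfs <- data.frame(y = rep(c(0, 1), each = 20),
                    x = rep(c(0, 1), each = 20))
  expect_warning(
    fit_glmm(glmm_spec("binomial", response = "y", fixed = "x",
                       groups = character(0), trials = 1), dfs),
    "separation")
})

test_that("profile intervals bracket the estimate and approach Wald asymptotically", {
  hh <- make_household_map(300, 240, seed = 33)
  pan <- simulate_frailty_panel(frailty_params(0.8, 0.4, 0.3), hh, 10,
                                seed = 33)
  fit <- fit_frailty(pan)
  ci <- profile_ci(fit, "(Intercept)")
  est <- unname(fit$coefficients[1])
  expect_lt(ci["lower"], est); expect_gt(ci["upper"], est)
  wald_width <- 2 * qnorm(0.975) * fit$se_fixed[1]
  expect_lt(abs((ci["upper"] - ci["lower"]) / wald_width - 1), 0.05)
})

test_that("variance decomposition obeys its structural identities", {
  hh <- make_household_map(250, 100, seed = 35)
  pan <- simulate_frailty_panel(frailty_params(0.8, 0.4, 0.3), hh, 8,
                                seed = 35)
  fit <- fit_frailty(pan)
  vd <- variance_decomposition(fit)
  # intercept-only: no fixed variance, adjusted ICC = conditional R2
  expect_equal(vd$marginal_r2, 0)
  expect_equal(vd$adjusted_icc, vd$conditional_r2)
  expect_gte(vd$conditional_r2, vd$marginal_r2)
  expect_lte(vd$conditional_r2, 1)
  # stronger household heterogeneity raises the adjusted ICC
  pan2 <- simulate_frailty_panel(frailty_params(0.8, 0.4, 0.8), hh, 8,
                                 seed = 35)
  vd2 <- variance_decomposition(fit_frailty(pan2))
  expect_gt(vd2$adjusted_icc, vd$adjusted_icc)
  # no random effects: decomposition is undefined
  glm0 <- fit_glmm(glmm_spec("poisson", response = "y",
                             groups = character(0)),
                   data.frame(y = c(1, 2, 0)))
  expect_error(variance_decomposition(glm0), "random effects")
})

test_that("Gauss-Hermite rules match an independent implementation", {
  skip_if_not_installed("pracma")
  for (n in c(5, 15)) {
    gh <- gauss_hermite(n)
    ref <- pracma::gaussHermite(n)
    expect_equal(gh$x, ref$x, tolerance = 1e-10)
    expect_equal(gh$w, ref$w, tolerance = 1e-10)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  hh <- make_household_map(150, 60, seed = 37)
  pan <- simulate_frailty_panel(frailty_params(0.9, 0.4, 0.3), hh, 8,
                                seed = 37)
  fit <- fit_frailty(pan)
  df <- data.frame(y = pan$count, f1 = factor(pan$id),
                   f2 = factor(pan$hh_id))
  g <- glmmTMB::glmmTMB(y ~ 1 + (1 | f1) + (1 | f2), family = stats::poisson,
                        data = df)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[1]),
               unname(glmmTMB::fixef(g)$cond[1]), tolerance = 1e-3)
  expect_equal(unname(sort(fit$sd)),
               unname(sort(sqrt(unlist(glmmTMB::VarCorr(g)$cond)))),
               tolerance = 0.02)
})
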