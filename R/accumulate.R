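#' Convert an event panel to a count panel
#'
#' Sums the event indicators per person-year. Missing indicators are
#' counted as not having occurred (equivalent to
#' [impute_missing_as_zero()]).
#'
#' @param panel an `ale_panel`.
#' @return a count `ale_panel`.
#' @export
as_count_panel <- function(panel) {
  if (is_count_panel(panel)) return(panel)
  out <- tibble::tibble(id = panel$id, hh_id = panel$hh_id,
                        year = panel$year,
                        count = yearly_counts(panel, na.rm = TRUE))
  if ("age" %in% names(panel)) out$age <- panel$age
  ale_panel(out, catalog = NULL, provenance = attr(panel, "provenance"),
            validate = FALSE)
}

# collapse exchangeable rows into weighted rows for the intercept-only fits
aggregate_weighted <- function(df) {
  key <- do.call(paste, c(df, sep = "\r"))
  tab <- table(key)
  out <- df[match(names(tab), key), , drop = FALSE]
  out$weight <- as.vector(tab)
  out
}

accum_data <- function(panel) {
  data.frame(y = yearly_counts(panel),
             individual = panel$id, household = panel$hh_id)
}

#' The "bad luck" accumulation model: homogeneous Poisson
#'
#' Intercept-only Poisson GLM: one rate for everyone, no random effects.
#' The rate estimate equals the sample mean count.
#'
#' @param panel an `ale_panel` (event panels are converted to counts).
#' @param control a [glmm_control()].
#' @return an `ale_glmm_fit`.
#' @export
fit_bad_luck <- function(panel, control = glmm_control()) {
  df <- aggregate_weighted(accum_data(panel)["y"])
  spec <- glmm_spec("poisson", response = "y", groups = character(0))
  fit <- fit_glmm(spec, df, weights = df$weight, control = control)
  if (sum(df$y * df$weight) == 0) fit$flags <- c(fit$flags, "all_zero_counts")
  fit
}

#' The frailty accumulation model: crossed log-normal heterogeneity
#'
#' Intercept-only Poisson mixed model with crossed individual and household
#' random intercepts: risk varies across entities but, given the frailties,
#' events are independent over time.
#'
#' @inheritParams fit_bad_luck
#' @return an `ale_glmm_fit`.
#' @export
fit_frailty <- function(panel, control = glmm_control()) {
  df <- aggregate_weighted(accum_data(panel))
  spec <- glmm_spec("poisson", response = "y",
                    groups = c("individual", "household"))
  fit_glmm(spec, df, weights = df$weight, control = control)
}

#' The Polya-urn accumulation model: beta-binomial with crossed intercepts
#'
#' Yearly counts are modelled as beta-binomial successes out of the
#' catalog's `k_trials` possible events (failures = possible events minus
#' successes), with crossed individual and household random intercepts.
#' This is the estimable surrogate of the literal urn: the beta-binomial
#' is the exchangeable law of urn totals, with mean `mu` and dispersion
#' `phi` in the Morris parameterization.
#'
#' @inheritParams fit_bad_luck
#' @param catalog the [ale_catalog()] supplying `k_trials` (never inferred
#'   from data maxima).
#' @return an `ale_glmm_fit`.
#' @export
fit_polya <- function(panel, catalog, control = glmm_control()) {
  df0 <- accum_data(panel)
  k <- catalog$k_trials
  if (any(df0$y > k))
    stop_ale("count exceeds k_trials = %d in rows: %s", k,
             paste(head(which(df0$y > k), 10), collapse = ", "))
  df <- aggregate_weighted(df0)
  spec <- glmm_spec("betabinomial", response = "y",
                    groups = c("individual", "household"), trials = k)
  fit_glmm(spec, df, weights = df$weight, control = control)
}

#' Compare the three accumulation processes
#'
#' Fits the homogeneous Poisson ("bad luck"), crossed-frailty, and
#' Polya-urn (beta-binomial) models to the same panel and tabulates fit
#' differences in the orientation `delta = fit(left) - fit(right)` for the
#' pairs (Poisson, Frailty) and (Frailty, Polya): a positive delta means
#' the model on the right fits better.
#'
#' @inheritParams fit_polya
#' @return a list of class `accumulation_comparison`: `fits` (named list),
#'   `comparison` (tibble of ordered-pair deltas), `winner_aic`,
#'   `winner_bic`.
#' @export
compare_accumulation <- function(panel, catalog, control = glmm_control()) {
  fits <- list(poisson = fit_bad_luck(panel, control),
               frailty = fit_frailty(panel, control),
               polya = fit_polya(panel, catalog, control))
  pairs <- list(c("poisson", "frailty"), c("frailty", "polya"))
  comparison <- do.call(rbind, lapply(pairs, function(pr) {
    tibble::tibble(left = pr[1], right = pr[2],
                   delta_aic = fits[[pr[1]]]$AIC - fits[[pr[2]]]$AIC,
                   delta_bic = fits[[pr[1]]]$BIC - fits[[pr[2]]]$BIC)
  }))
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  bics <- vapply(fits, `[[`, numeric(1), "BIC")
  structure(list(fits = fits, comparison = comparison,
                 winner_aic = names(which.min(aics)),
                 winner_bic = names(which.min(bics))),
            class = "accumulation_comparison")
}

#' @method print accumulation_comparison
#' @export
print.accumulation_comparison <- function(x, ...) {
  cat("<accumulation_comparison>\n")
  print(as.data.frame(x$comparison))
  cat("preferred by AIC:", x$winner_aic, "| by BIC:", x$winner_bic, "\n")
  invisible(x)
}

#' Forward-simulate a fitted accumulation model
#'
#' Simulates `reps` fresh populations from the fitted parameters, redrawing
#' random intercepts from the fitted SDs (a new population, not the
#' estimated entities), and returns the histogram of cumulative counts per
#' year for envelope plots against the empirical distribution.
#'
#' @param fit an `ale_glmm_fit` from one of the three accumulation models.
#' @param catalog the [ale_catalog()] (trial count for the beta-binomial).
#' @param n_individuals,n_years population size and horizon per replicate.
#' @param reps number of simulated populations.
#' @param seed integer seed.
#' @return a tibble `rep`, `year`, `count` (cumulative), `n` (individuals
#'   at that cumulative count).
#' @export
simulate_fitted <- function(fit, catalog, n_individuals, n_years,
                            reps = 1000, seed = 1) {
  kind <- if (fit$family == "betabinomial") "polya"
          else if (length(fit$sd)) "frailty" else "poisson"
  n <- n_individuals
  set.seed(substream_seed(seed, "simulate_fitted"))
  if (length(fit$sd)) {
    sd_i <- if ("individual" %in% names(fit$sd)) fit$sd[["individual"]] else 0
    sd_h <- if ("household" %in% names(fit$sd)) fit$sd[["household"]] else 0
  } else sd_i <- sd_h <- 0
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    re <- rnorm(n, 0, sd_i) + rnorm(n, 0, sd_h) # fresh entities each rep
    counts <- switch(kind,
      poisson = matrix(rpois(n * n_years, exp(fit$coefficients[1])),
                       nrow = n),
      frailty = {
        rate <- exp(fit$coefficients[1] + re)
        matrix(rpois(n * n_years, rep(rate, n_years)), nrow = n)
      },
      polya = {
        mu <- plogis(fit$coefficients[1] + re)
        k <- catalog$k_trials
        p <- rbeta(n * n_years, rep(mu, n_years) * fit$phi,
                   rep(1 - mu, n_years) * fit$phi)
        matrix(rbinom(n * n_years, k, p), nrow = n)
      })
    cum <- t(apply(counts, 1, cumsum))
    if (n_years == 1) cum <- matrix(counts, ncol = 1)
    tabs <- lapply(seq_len(n_years), function(t_) {
      tb <- table(cum[, t_])
      tibble::tibble(rep = r, year = t_,
                     count = as.integer(names(tb)), n = as.integer(tb))
    })
    out[[r]] <- do.call(rbind, tabs)
  }
  do.call(rbind, out)
}

#' Lag-1 autocorrelation of yearly event counts
#'
#' Poisson mixed model of this year's count on last year's count plus a
#' quadratic age trend, with crossed individual and household random
#' intercepts: `count ~ 1 + age + age^2 + lag-1 count + (1 | individual) +
#' (1 | household)`. Age is standardized (mean 0, SD 1) on the analysis
#' rows and squared after standardization; the lagged count enters
#' unscaled. Use [glmm_estimates()] with `natural = TRUE` for rate-ratio
#' estimates: a natural-scale lag coefficient `e_b` means each additional
#' prior event multiplies this year's rate by `e_b`, i.e. a
#' `(e_b - 1) * 100` percent increase.
#'
#' @param panel an `ale_panel` with `age`.
#' @param control a [glmm_control()].
#' @return an `ale_glmm_fit`; the age standardization constants are stored
#'   in `$age_scaling`.
#' @export
fit_autocorrelation <- function(panel, control = glmm_control()) {
  cp <- as_count_panel(panel)
  if (!"age" %in% names(cp)) stop_ale("age required for the autocorrelation model")
  al <- lag_align(cp)
  if (!nrow(al)) stop_ale("no adjacent year pairs to align")
  mu_age <- mean(al$age); sd_age <- sd(al$age)
  if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
  df <- data.frame(y = al$count_out,
                   age_z = (al$age - mu_age) / sd_age,
                   lag_count = al$count_lag,
                   individual = al$id, household = al$hh_id)
  df$age_z2 <- df$age_z^2
  spec <- glmm_spec("poisson", response = "y",
                    fixed = c("age_z", "age_z2", "lag_count"),
                    groups = c("individual", "household"))
  fit <- fit_glmm(spec, df, control = control)
  fit$age_scaling <- c(mean = mu_age, sd = sd_age)
  fit
}
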