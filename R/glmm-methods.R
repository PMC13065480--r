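#' @method print ale_glmm_fit
#' @export
print.ale_glmm_fit <- function(x, ...) {
  cat("<ale_glmm_fit> family =", x$family,
      "| n_obs =", x$n_obs, "|", x$convergence, "\n")
  est <- x$coefficients
  cat("fixed effects (link scale):\n")
  print(round(est, 4))
  if (length(x$sd)) {
    cat("random-intercept SDs:\n")
    print(round(x$sd, 4))
  }
  if (!is.null(x$phi)) cat("dispersion phi =", round(x$phi, 3), "\n")
  cat(sprintf("logLik = %.3f  AIC = %.2f  BIC = %.2f  (df = %d)\n",
              x$loglik, x$AIC, x$BIC, x$df))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.ale_glmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.ale_glmm_fit <- function(object, ...) object$coefficients

#' Parameter table of a mixed-model fit
#'
#' @param fit an `ale_glmm_fit`.
#' @param level confidence level for Wald intervals.
#' @param natural exponentiate fixed effects (rate ratios / odds ratios);
#'   SDs and phi are already on their natural scale.
#' @return a tibble with `term`, `estimate`, `conf_low`, `conf_high`,
#'   `type`.
#' @export
glmm_estimates <- function(fit, level = 0.95, natural = FALSE) {
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients; se <- fit$se_fixed
  lo <- b - z * se; hi <- b + z * se
  if (natural) { b <- exp(b); lo <- exp(lo); hi <- exp(hi) }
  out <- tibble::tibble(term = names(fit$coefficients), estimate = b,
                        conf_low = lo, conf_high = hi, type = "fixed")
  nG <- length(fit$sd)
  if (nG > 0 || !is.null(fit$phi)) {
    se_th <- sqrt(pmax(diag(fit$vcov_theta), 0))
    th <- fit$theta
    nat <- exp(th); tlo <- exp(th - z * se_th); thi <- exp(th + z * se_th)
    labs <- c(if (nG) paste0("sd_", names(fit$sd)),
              if (!is.null(fit$phi)) "phi")
    out <- rbind(out, tibble::tibble(
      term = labs, estimate = nat, conf_low = tlo, conf_high = thi,
      type = ifelse(labs == "phi", "dispersion", "random")))
  }
  out
}

# maximize the Laplace objective with one parameter pinned; returns loglik
profile_refit <- function(fit, target, value) {
  dat <- fit$internals$dat
  control <- fit$control
  nG <- length(dat$grp)
  has_phi <- fit$family == "betabinomial"
  p <- dat$p
  th_names <- c(if (nG) paste0("sd_", names(dat$grp)),
                if (has_phi) "phi")
  full <- c(fit$coefficients, fit$theta)
  names(full) <- c(names(fit$coefficients), th_names)
  if (!target %in% names(full))
    stop_ale("unknown parameter '%s'", target)
  ti <- match(target, names(full))
  is_theta <- ti > p
  fixed_val <- if (is_theta) log(value) else value
  if (is_theta && value <= 0) fixed_val <- control$sd_log_lower
  free_idx <- setdiff(seq_along(full), ti)
  state <- new.env(parent = emptyenv())
  state$u <- fit$internals$state$u
  obj <- function(par) {
    all_par <- numeric(length(full))
    all_par[free_idx] <- par
    all_par[ti] <- fixed_val
    beta <- all_par[seq_len(p)]
    th <- all_par[-seq_len(p)]
    sdv <- if (nG) exp(th[seq_len(nG)]) else numeric(0)
    phi <- if (has_phi) exp(th[length(th)]) else NULL
    sol <- inner_newton(dat, beta, sdv, phi, state, control)
    if (!sol$ok || !is.finite(sol$f)) return(1e10)
    -laplace_value(dat, sol, sdv)
  }
  lower <- c(rep(-Inf, p), rep(control$sd_log_lower, nG),
             if (has_phi) -5)[free_idx]
  upper <- c(rep(Inf, p), rep(5, nG),
             if (has_phi) control$phi_log_upper)[free_idx]
  opt <- nlminb(full[free_idx], obj, lower = lower, upper = upper,
                control = list(rel.tol = control$rel_tol, iter.max = 200))
  -opt$objective
}

#' Profile likelihood confidence interval
#'
#' Endpoint search on the signed likelihood-ratio statistic against the
#' chi-square(1) quantile: the deviance `2 * (loglik_max - loglik_profile)`
#' is bracketed outward from the Wald endpoint and the crossing located by
#' root finding. Fixed effects are profiled on the link scale, variance
#' parameters on the log-SD scale. A random-intercept SD whose profile
#' never crosses the threshold before the boundary gets lower endpoint 0.
#'
#' @param fit a converged `ale_glmm_fit`.
#' @param parameter a fixed-effect name (e.g. `"(Intercept)"`), an SD name
#'   (`"sd_individual"`, `"sd_household"`), or `"phi"`.
#' @param level confidence level.
#' @return length-2 numeric: lower and upper endpoints, on the link scale
#'   for fixed effects and the natural scale for SDs/phi.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  if (!grepl("^converged", fit$convergence))
    stop_ale("profile intervals need a converged fit")
  crit <- qchisq(level, 1)
  llmax <- fit$loglik
  p <- length(fit$coefficients)
  is_theta <- !parameter %in% names(fit$coefficients)
  if (is_theta) {
    th_names <- c(if (length(fit$sd)) paste0("sd_", names(fit$sd)),
                  if (!is.null(fit$phi)) "phi")
    k <- match(parameter, th_names)
    if (is.na(k)) stop_ale("unknown parameter '%s'", parameter)
    est <- fit$theta[k] # log scale
    se <- sqrt(pmax(diag(fit$vcov_theta), 1e-4))[k]
    to_value <- exp
    dev_at <- function(v) 2 * (llmax - profile_refit(fit, parameter, exp(v)))
  } else {
    k <- match(parameter, names(fit$coefficients))
    est <- fit$coefficients[k]
    se <- max(fit$se_fixed[k], 1e-4)
    to_value <- identity
    dev_at <- function(v) 2 * (llmax - profile_refit(fit, parameter, v))
  }
  lb <- if (is_theta) fit$control$sd_log_lower else -Inf
  one_side <- function(dir) {
    step <- 1.2 * se
    prev <- est
    for (j in 1:14) {
      v <- est + dir * step
      if (is_theta && v <= lb) {
        if (dev_at(lb) < crit) return(if (dir < 0) -Inf else Inf)
        v <- lb + 1e-3
      }
      d <- dev_at(v)
      if (!is.finite(d)) stop_ale("profile evaluation failed at %g", v)
      if (d >= crit) {
        r <- uniroot(function(x) dev_at(x) - crit, lower = min(prev, v),
                     upper = max(prev, v), tol = se * 1e-3)
        return(r$root)
      }
      prev <- v
      step <- step * 1.7
    }
    stop_ale("profile deviance did not reach the threshold; bracket failure")
  }
  lo <- one_side(-1)
  hi <- one_side(1)
  lo <- if (identical(lo, -Inf)) { if (is_theta) 0 else -Inf } else to_value(lo)
  hi <- if (identical(hi, Inf)) Inf else to_value(hi)
  c(lower = lo, upper = hi)
}

#' Latent-scale variance decomposition
#'
#' Splits the latent (link-scale) variance into fixed, random, and residual
#' components: marginal R-squared = var_fixed / total, conditional
#' R-squared adds the random-intercept variance to the numerator, and the
#' adjusted ICC is the random share of the non-fixed variance. The
#' family-specific residual variance uses the log-normal approximation
#' `log(1 + 1/lambda_bar)` for the Poisson log link (with `lambda_bar` the
#' marginal mean rate) and `pi^2 / 3` for the logit links. In an
#' intercept-only model the marginal R-squared is zero and the adjusted ICC
#' equals the conditional R-squared.
#'
#' @param fit an `ale_glmm_fit` with at least one random intercept.
#' @return a tibble with `marginal_r2`, `conditional_r2`, `adjusted_icc`
#'   and the three variance components.
#' @export
variance_decomposition <- function(fit) {
  if (!length(fit$sd)) stop_ale("fit has no random effects to decompose")
  dat <- fit$internals$dat
  lp <- as.vector(dat$X %*% fit$coefficients)
  wbar <- dat$w / sum(dat$w)
  var_fixed <- sum(wbar * (lp - sum(wbar * lp))^2)
  var_random <- sum(fit$sd^2)
  var_resid <- switch(fit$family,
    poisson = {
      lambda_bar <- sum(wbar * exp(lp)) * exp(0.5 * var_random)
      log(1 + 1 / lambda_bar)
    },
    binomial = pi^2 / 3,
    betabinomial = pi^2 / 3)
  tot <- var_fixed + var_random + var_resid
  tibble::tibble(
    marginal_r2 = var_fixed / tot,
    conditional_r2 = (var_fixed + var_random) / tot,
    adjusted_icc = var_random / (var_random + var_resid),
    var_fixed = var_fixed, var_random = var_random, var_resid = var_resid)
}
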