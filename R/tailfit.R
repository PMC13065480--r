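#' Remove zero cumulative counts before tail fitting
#'
#' Heavy-tailed models are fitted to strictly positive cumulative counts;
#' people with zero events are excluded and the removal count reported.
#'
#' @param counts non-negative integer counts.
#' @return the positive counts, with the number removed in
#'   `attr(, "removed")`.
#' @export
exclude_zeros <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop_ale("counts must be non-negative integers")
  out <- counts[counts > 0]
  if (!length(out)) stop_ale("all counts are zero; nothing to fit")
  structure(out, removed = sum(counts == 0))
}

# Euler-Maclaurin Hurwitz zeta: sum_{k>=0} (q + k)^(-a)
hurwitz_zeta <- function(a, q, terms = 1000L) {
  k <- 0:(terms - 1)
  tail_q <- q + terms
  sum((q + k)^(-a)) + tail_q^(1 - a) / (a - 1) + 0.5 * tail_q^(-a) +
    a * tail_q^(-a - 1) / 12
}

# distribution dialect registry: discrete power-law and Poisson, continuous
# exponential and log-normal truncated at xmin
tail_family <- function(distribution) {
  switch(distribution,
    powerlaw = list(
      discrete = TRUE,
      fit = function(x, xmin) {
        slx <- sum(log(x))
        nll <- function(a) length(x) * log(hurwitz_zeta(a, xmin)) + a * slx
        opt <- optimize(nll, c(1.01, 25))
        list(pars = c(exponent = opt$minimum), loglik = -opt$objective)
      },
      logpdf = function(x, pars, xmin)
        -pars[["exponent"]] * log(x) -
          log(hurwitz_zeta(pars[["exponent"]], xmin)),
      cdf = function(x, pars, xmin) {
        hz0 <- hurwitz_zeta(pars[["exponent"]], xmin)
        vapply(x, function(v)
          1 - hurwitz_zeta(pars[["exponent"]], v + 1) / hz0, numeric(1))
      }),
    exponential = list(
      discrete = FALSE,
      fit = function(x, xmin) {
        if (mean(x) <= xmin) stop_ale("degenerate tail for the exponential fit")
        rate <- 1 / (mean(x) - xmin)
        list(pars = c(rate = rate),
             loglik = sum(log(rate) - rate * (x - xmin)))
      },
      logpdf = function(x, pars, xmin)
        log(pars[["rate"]]) - pars[["rate"]] * (x - xmin),
      cdf = function(x, pars, xmin) 1 - exp(-pars[["rate"]] * (x - xmin))),
    lognormal = list(
      discrete = FALSE,
      fit = function(x, xmin) {
        lx <- log(x)
        if (sd(lx) == 0) stop_ale("degenerate tail for the log-normal fit")
        nll <- function(p) {
          m <- p[1]; s <- exp(p[2])
          z0 <- (log(xmin) - m) / s
          surv <- pnorm(z0, lower.tail = FALSE)
          if (surv <= 0) return(1e10)
          -sum(stats::dlnorm(x, m, s, log = TRUE)) + length(x) * log(surv)
        }
        opt <- optim(c(mean(lx), log(max(sd(lx), 0.05))), nll,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
        list(pars = c(meanlog = opt$par[1], sdlog = exp(opt$par[2])),
             loglik = -opt$value)
      },
      logpdf = function(x, pars, xmin) {
        z0 <- (log(xmin) - pars[["meanlog"]]) / pars[["sdlog"]]
        stats::dlnorm(x, pars[["meanlog"]], pars[["sdlog"]], log = TRUE) -
          pnorm(z0, lower.tail = FALSE, log.p = TRUE)
      },
      cdf = function(x, pars, xmin) {
        s0 <- stats::plnorm(xmin, pars[["meanlog"]], pars[["sdlog"]],
                            lower.tail = FALSE)
        pmax(0, (stats::plnorm(x, pars[["meanlog"]], pars[["sdlog"]]) -
                   (1 - s0)) / s0)
      }),
    poisson = list(
      discrete = TRUE,
      fit = function(x, xmin) {
        nll <- function(l)
          -sum(dpois(x, l, log = TRUE)) +
            length(x) * stats::ppois(xmin - 1, l, lower.tail = FALSE,
                                     log.p = TRUE)
        opt <- optimize(nll, c(1e-3, 2 * max(x) + 5))
        list(pars = c(lambda = opt$minimum), loglik = -opt$objective)
      },
      logpdf = function(x, pars, xmin)
        dpois(x, pars[["lambda"]], log = TRUE) -
          stats::ppois(xmin - 1, pars[["lambda"]], lower.tail = FALSE,
                       log.p = TRUE),
      cdf = function(x, pars, xmin) {
        s0 <- stats::ppois(xmin - 1, pars[["lambda"]], lower.tail = FALSE)
        (stats::ppois(x, pars[["lambda"]]) -
           stats::ppois(xmin - 1, pars[["lambda"]])) / s0
      }),
    stop_ale("unknown distribution '%s'", distribution))
}

ks_statistic <- function(x, fam, pars, xmin) {
  xs <- sort(unique(x))
  emp <- stats::ecdf(x)(xs)
  mod <- fam$cdf(xs, pars, xmin)
  max(abs(emp - mod))
}

#' Fit a tail distribution above a threshold
#'
#' Maximum-likelihood fit of one of four models to the counts at or above
#' `xmin`: discrete power-law (normalized by the Hurwitz zeta sum),
#' truncated Poisson, and continuous exponential and log-normal truncated
#' at `xmin` (the convention of the standard heavy-tail fitting toolkit;
#' the dialect is recorded in the result).
#'
#' @param counts positive integer counts.
#' @param distribution one of `"powerlaw"`, `"exponential"`,
#'   `"lognormal"`, `"poisson"`.
#' @param xmin the lower threshold; must be an observed value.
#' @return an `ale_tailfit`: `distribution`, `pars`, `xmin`, `ks`,
#'   `n_tail`, `loglik`, `discrete`.
#' @export
fit_tail <- function(counts, distribution, xmin) {
  if (!xmin %in% counts) stop_ale("xmin must be an observed value")
  x <- counts[counts >= xmin]
  if (length(unique(x)) < 2) stop_ale("degenerate tail: single repeated value")
  fam <- tail_family(distribution)
  ft <- fam$fit(x, xmin)
  structure(list(distribution = distribution, pars = ft$pars, xmin = xmin,
                 ks = ks_statistic(x, fam, ft$pars, xmin),
                 n_tail = length(x), loglik = ft$loglik,
                 discrete = fam$discrete),
            class = "ale_tailfit")
}

#' @method print ale_tailfit
#' @export
print.ale_tailfit <- function(x, ...) {
  cat(sprintf("<ale_tailfit> %s (%s), xmin = %g, n_tail = %d\n",
              x$distribution, if (x$discrete) "discrete" else "continuous",
              x$xmin, x$n_tail))
  print(round(x$pars, 4))
  cat(sprintf("KS = %.4f  loglik = %.2f\n", x$ks, x$loglik))
  invisible(x)
}

#' Estimate the tail threshold by minimizing the KS statistic
#'
#' For every candidate `xmin` among the observed values, fits the model to
#' the tail by maximum likelihood and computes the Kolmogorov-Smirnov
#' distance between the fitted and empirical tail CDFs; returns the
#' minimizer, breaking ties toward the smallest `xmin`.
#'
#' @param counts positive integer counts.
#' @param distribution as in [fit_tail()].
#' @param min_tail smallest admissible number of tail observations for a
#'   candidate.
#' @return list with `xmin`, `ks`, and the `fit` at the optimum.
#' @export
estimate_xmin <- function(counts, distribution, min_tail = 4) {
  u <- sort(unique(counts))
  if (length(u) < 2) stop_ale("need at least two distinct values")
  if (length(u) < 10)
    warning("fewer than 10 distinct values; threshold estimate is crude")
  cand <- u[vapply(u, function(v) {
    xt <- counts[counts >= v]
    length(xt) >= min_tail && length(unique(xt)) >= 2
  }, logical(1))]
  if (!length(cand)) cand <- u[1]
  ks <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    ks[i] <- tryCatch(fit_tail(counts, distribution, cand[i])$ks,
                      error = function(e) NA_real_)
  }
  if (all(is.na(ks))) stop_ale("no candidate threshold admitted a fit")
  best <- cand[which.min(ks)] # which.min takes the first (smallest) on ties
  list(xmin = best, ks = min(ks, na.rm = TRUE),
       fit = fit_tail(counts, distribution, best))
}

#' Vuong's likelihood-ratio test for non-nested tail models
#'
#' Both models are re-fitted at a common threshold: the median of the two
#' estimated thresholds (the mean when they differ), rounded down to the
#' nearest observed value. The statistic is the normalized sum of
#' pointwise log-likelihood differences over the common tail,
#' `sqrt(n) * mean(d) / sd(d)`; under the null that both models are
#' equally far from the truth it is asymptotically standard normal, and a
#' positive value favours the first model. Identical pointwise
#' likelihoods give statistic 0 and p = 1.
#'
#' @param fit_a,fit_b `ale_tailfit` objects (their distributions are
#'   re-fitted at the common threshold).
#' @param counts the positive integer counts both models describe.
#' @return a `vuong_result`: `statistic`, `p_value`, `xmin`, `n_tail`,
#'   per-model tail log-likelihoods.
#' @export
vuong_compare <- function(fit_a, fit_b, counts) {
  xm <- mean(c(fit_a$xmin, fit_b$xmin))
  obs <- sort(unique(counts))
  xm <- max(obs[obs <= xm], obs[1])
  fa <- fit_tail(counts, fit_a$distribution, xm)
  fb <- fit_tail(counts, fit_b$distribution, xm)
  x <- counts[counts >= xm]
  if (length(x) < 3) stop_ale("common tail has fewer than 3 observations")
  if (length(x) < 10) warning("common tail has fewer than 10 observations")
  la <- tail_family(fa$distribution)$logpdf(x, fa$pars, xm)
  lb <- tail_family(fb$distribution)$logpdf(x, fb$pars, xm)
  d <- la - lb
  sdd <- sd(d)
  if (!is.finite(sdd) || sdd < 1e-12) {
    stat <- 0; p <- 1
  } else {
    stat <- sqrt(length(d)) * mean(d) / sdd
    p <- 2 * pnorm(abs(stat), lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, xmin = xm,
                 n_tail = length(x),
                 loglik_a = sum(la), loglik_b = sum(lb),
                 model_a = fa$distribution, model_b = fb$distribution),
            class = "vuong_result")
}

#' @method print vuong_result
#' @export
print.vuong_result <- function(x, ...) {
  cat(sprintf(
    "<vuong_result> %s vs %s at xmin = %g (n = %d): statistic = %.3f, p = %.4g\n",
    x$model_a, x$model_b, x$xmin, x$n_tail, x$statistic, x$p_value))
  invisible(x)
}
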