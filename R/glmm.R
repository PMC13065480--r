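#' Mixed-model specification
#'
#' Describes a regression of a person-year response on fixed covariates with
#' crossed random intercepts, in one of three families: Poisson counts (log
#' link), binomial successes out of a fixed trial count (logit link), or
#' beta-binomial successes in the mean/dispersion ("Morris")
#' parameterization, `mean = plogis(eta)`, dispersion `phi` on the log
#' scale, variance `mu(1-mu) * n(phi+n)/(phi+1)` for `n` trials.
#'
#' @param family `"poisson"`, `"binomial"`, or `"betabinomial"`.
#' @param response name of the response column (counts, or successes for the
#'   binomial families).
#' @param fixed character vector of fixed covariate column names; the
#'   intercept is implicit.
#' @param groups character vector of grouping-factor column names (0, 1 or 2
#'   of them; typically `c("individual", "household")`).
#' @param trials trial count for the binomial families: a single number or
#'   the name of a column.
#' @return an object of class `glmm_spec`.
#' @export
glmm_spec <- function(family = c("poisson", "binomial", "betabinomial"),
                      response = "y", fixed = character(0),
                      groups = c("individual", "household"),
                      trials = NULL) {
  family <- match.arg(family)
  if (family != "poisson" && is.null(trials))
    stop_ale("trials required for the (beta-)binomial families")
  if (family == "poisson" && !is.null(trials))
    stop_ale("trials only apply to the (beta-)binomial families")
  if (length(groups) > 2) stop_ale("at most two crossed grouping factors")
  structure(list(family = family, response = response, fixed = fixed,
                 groups = groups, trials = trials),
            class = "glmm_spec")
}

#' Numerical control for the mixed-model fitter
#'
#' @param rel_tol relative convergence tolerance of the outer optimizer.
#' @param max_iter maximum outer iterations.
#' @param inner_max maximum damped-Newton iterations for the random-effect
#'   mode.
#' @param inner_tol gradient tolerance of the inner Newton solver.
#' @param restarts number of jittered restarts on non-convergence (seeded).
#' @param multistart for beta-binomial mixed fits, also try a start in the
#'   persistent-heterogeneity regime (sigma > 0, phi at its upper bound)
#'   and keep the better optimum; the surface has two canonical modes.
#' @param full_vcov_max up to this many total parameters (fixed + variance),
#'   Wald covariance uses the full joint observed information of the
#'   Laplace objective; above it, fixed-effect covariance is conditional
#'   on the variance parameters (cheaper, as in lme4).
#' @param polish after the fast profiled optimization, re-optimize all
#'   parameters jointly on the exact Laplace objective.
#' @param sd_log_lower lower bound for log random-intercept SDs; reaching it
#'   is reported as a boundary (sigma approximately 0) fit.
#' @param phi_log_upper upper bound for the log beta-binomial dispersion;
#'   reaching it signals no detectable overdispersion (binomial limit).
#' @return a list of class `glmm_control`.
#' @export
glmm_control <- function(rel_tol = 1e-8, max_iter = 200, inner_max = 50,
                         inner_tol = 1e-8, restarts = 3, polish = TRUE,
                         sd_log_lower = -10, phi_log_upper = 16,
                         multistart = TRUE, full_vcov_max = 6) {
  structure(list(rel_tol = rel_tol, max_iter = max_iter,
                 inner_max = inner_max, inner_tol = inner_tol,
                 restarts = restarts, polish = polish,
                 sd_log_lower = sd_log_lower, phi_log_upper = phi_log_upper,
                 multistart = multistart, full_vcov_max = full_vcov_max),
            class = "glmm_control")
}

# ---- family derivatives ----------------------------------------------------
# log-likelihood and its first two derivatives w.r.t. the linear predictor
fam_derivs <- function(family, y, m, eta, phi = NULL, deriv = 2L) {
  if (family == "poisson") {
    mu <- exp(eta)
    out <- list(ll = y * eta - mu - lfactorial(y))
    if (deriv >= 1) { out$d1 <- y - mu; out$d2 <- -mu }
  } else if (family == "binomial") {
    p <- plogis(eta)
    out <- list(ll = y * eta - m * log1pexp(eta) + lchoose(m, y))
    if (deriv >= 1) { out$d1 <- y - m * p; out$d2 <- -m * p * (1 - p) }
  } else { # betabinomial, Morris mu/phi
    mu <- plogis(eta)
    a <- mu * phi; b <- (1 - mu) * phi
    out <- list(ll = lchoose(m, y) + lgamma(y + a) + lgamma(m - y + b) -
                  lgamma(m + phi) - lgamma(a) - lgamma(b) + lgamma(phi))
    if (deriv >= 1) {
      s <- phi * mu * (1 - mu)
      g <- digamma(y + a) - digamma(a) - digamma(m - y + b) + digamma(b)
      out$d1 <- s * g
      gp <- trigamma(y + a) - trigamma(a) + trigamma(m - y + b) - trigamma(b)
      out$d2 <- s * (1 - 2 * mu) * g + s^2 * gp
    }
  }
  out
}

# ---- data preparation ------------------------------------------------------
prepare_glmm_data <- function(spec, data, weights = NULL) {
  data <- as.data.frame(data)
  y <- data[[spec$response]]
  if (is.null(y)) stop_ale("response column '%s' not found", spec$response)
  if (any(y < 0) || any(y != round(y))) stop_ale("response must be counts")
  w <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(weights)
  m <- NULL
  if (spec$family != "poisson") {
    m <- if (is.character(spec$trials)) data[[spec$trials]]
         else rep(spec$trials, nrow(data))
    if (any(y > m)) stop_ale("successes exceed trials in rows: %s",
                             paste(head(which(y > m), 10), collapse = ", "))
  }
  miss <- setdiff(spec$fixed, names(data))
  if (length(miss)) stop_ale("fixed covariate(s) not found: %s",
                             paste(miss, collapse = ", "))
  X <- cbind(rep(1, nrow(data)),
             as.matrix(data[, spec$fixed, drop = FALSE]))
  colnames(X) <- c("(Intercept)", spec$fixed)
  groups <- intersect(spec$groups, names(data))
  if (length(groups) != length(spec$groups) && length(spec$groups))
    stop_ale("grouping column(s) not found: %s",
             paste(setdiff(spec$groups, names(data)), collapse = ", "))
  grp <- lapply(groups, function(g) {
    f <- factor(data[[g]])
    list(idx = as.integer(f), q = nlevels(f), levels = levels(f))
  })
  names(grp) <- groups
  qs <- vapply(grp, `[[`, integer(1), "q")
  offs <- c(0L, cumsum(qs))[seq_along(qs)]
  q <- sum(qs)
  # sparse lower-triangle pattern of the random-effect Hessian
  cell <- NULL
  if (length(grp) == 2L) {
    raw <- (grp[[1]]$idx - 1L) * grp[[2]]$q + grp[[2]]$idx
    f <- factor(raw)
    cell <- list(idx = as.integer(f),
                 i = (as.integer(levels(f)) - 1L) %/% grp[[2]]$q + 1L,
                 h = (as.integer(levels(f)) - 1L) %% grp[[2]]$q + 1L)
  }
  hpat <- NULL
  if (q > 0) {
    ti <- seq_len(q); tj <- seq_len(q)
    if (!is.null(cell)) {
      ti <- c(ti, offs[2] + cell$h) # household row (lower triangle)
      tj <- c(tj, cell$i)
    }
    H0 <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                               dims = c(q, q), symmetric = TRUE)
    hpat <- list(ti = ti, tj = tj, perm = as.integer(H0@x), H = H0)
  }
  list(y = as.numeric(y), m = m, w = w, X = X, p = ncol(X),
       grp = grp, qs = qs, offs = offs, q = q, cell = cell, hpat = hpat,
       n_obs = sum(w), n_rows = nrow(data))
}

group_sum <- function(v, idx, q) {
  out <- numeric(q)
  s <- rowsum(v, idx) # sorted unique idx; all levels present by construction
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

assemble_H <- function(dat, cvals, prec) {
  vals <- numeric(0)
  dvals <- prec
  for (g in seq_along(dat$grp))
    dvals[dat$offs[g] + seq_len(dat$qs[g])] <-
      dvals[dat$offs[g] + seq_len(dat$qs[g])] +
      group_sum(cvals, dat$grp[[g]]$idx, dat$qs[g])
  vals <- dvals
  if (!is.null(dat$cell))
    vals <- c(vals, group_sum(cvals, dat$cell$idx, length(dat$cell$i)))
  H <- dat$hpat$H
  H@x <- vals[dat$hpat$perm]
  H
}

# joint penalized log-likelihood pieces for current u (stacked REs)
joint_eta <- function(dat, beta, u) {
  eta <- as.vector(dat$X %*% beta)
  for (g in seq_along(dat$grp))
    eta <- eta + u[dat$offs[g] + dat$grp[[g]]$idx]
  eta
}

# Damped Newton for the random-effect mode (optionally with beta profiled
# into the inner optimization via a Schur complement on the sparse factor).
inner_newton <- function(dat, beta, sd_vec, phi, state, control,
                         profile_beta = FALSE) {
  active <- sd_vec > 1e-12
  q <- dat$q
  prec <- numeric(q)
  for (g in seq_along(dat$grp))
    prec[dat$offs[g] + seq_len(dat$qs[g])] <-
      if (active[g]) 1 / sd_vec[g]^2 else Inf
  u <- state$u
  if (is.null(u) || length(u) != q) u <- numeric(q)
  u[prec == Inf] <- 0
  if (profile_beta && !is.null(state$beta) &&
      length(state$beta) == length(beta)) beta <- state$beta
  free <- prec < Inf # REs actually integrated over
  pen <- function(u) -0.5 * sum((u^2 * prec)[free])
  fval <- function(eta, u) {
    d <- fam_derivs(dat$fam, dat$y, dat$m, eta, phi, deriv = 0L)
    sum(dat$w * d$ll) + pen(u)
  }
  eta <- joint_eta(dat, beta, u)
  f <- fval(eta, u)
  if (q == 0 && !profile_beta) {
    # nothing to optimize: the joint likelihood at beta is the GLM loglik
    return(list(ok = is.finite(f), u = u, beta = beta, eta = eta, f = f,
                logdet = 0, n_free = 0L, converged = TRUE, Ch = NULL,
                free = free, prec = prec))
  }
  if (!is.finite(f)) { u[] <- 0; eta <- joint_eta(dat, beta, u); f <- fval(eta, u) }
  Ch <- state$Ch
  conv <- FALSE
  ridge <- 0
  d_current <- FALSE
  cvals <- NULL
  for (it in seq_len(control$inner_max)) {
    d <- fam_derivs(dat$fam, dat$y, dat$m, eta, phi)
    d_current <- TRUE
    wd1 <- dat$w * d$d1
    cvals <- pmax(-dat$w * d$d2, 0)
    gu <- numeric(q)
    for (g in seq_along(dat$grp))
      gu[dat$offs[g] + seq_len(dat$qs[g])] <-
        group_sum(wd1, dat$grp[[g]]$idx, dat$qs[g])
    gu <- gu - u * ifelse(free, prec, 0)
    gu[!free] <- 0
    gb <- if (profile_beta) as.vector(crossprod(dat$X, wd1)) else NULL
    gnorm <- max(abs(c(gu, gb)), 0)
    if (gnorm < control$inner_tol * (1 + abs(f)) && it > 1) { conv <- TRUE; break }
    if (q > 0) {
      prec_eff <- ifelse(free, prec, 1e12) # pin excluded REs at 0
      H <- assemble_H(dat, cvals, prec_eff + ridge)
      Ch <- tryCatch({
        if (is.null(Ch)) Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
        else Matrix::update(Ch, H)
      }, error = function(e) NULL)
      if (is.null(Ch)) { ridge <- max(ridge * 10, 1e-4); next }
    }
    if (profile_beta) {
      Xc <- dat$X * cvals
      Hbb <- crossprod(dat$X, Xc)
      if (q > 0) {
        A <- matrix(0, q, dat$p)
        for (g in seq_along(dat$grp))
          for (k in seq_len(dat$p))
            A[dat$offs[g] + seq_len(dat$qs[g]), k] <-
              group_sum(Xc[, k], dat$grp[[g]]$idx, dat$qs[g])
        Tm <- as.matrix(Matrix::solve(Ch, A, system = "A"))
        S <- Hbb - crossprod(A, Tm)
        t1 <- as.vector(Matrix::solve(Ch, gu, system = "A"))
        db <- solve(S + diag(1e-10, dat$p), gb - crossprod(A, t1))
        du <- t1 - Tm %*% db
      } else {
        db <- solve(Hbb + diag(1e-10, dat$p), gb)
        du <- numeric(0)
      }
      step_u <- as.vector(du); step_b <- as.vector(db)
    } else {
      step_u <- as.vector(Matrix::solve(Ch, gu, system = "A"))
      step_b <- NULL
    }
    t_ <- 1
    repeat {
      u_new <- u + t_ * step_u
      u_new[!free] <- 0
      b_new <- if (profile_beta) beta + t_ * step_b else beta
      eta_new <- joint_eta(dat, b_new, u_new)
      f_new <- fval(eta_new, u_new)
      if (is.finite(f_new) && f_new >= f - 1e-10) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    if (t_ < 1e-10) { conv <- gnorm < 1e-4 * (1 + abs(f)); break }
    moved <- f_new - f
    u <- u + t_ * step_u; u[!free] <- 0
    if (profile_beta) beta <- beta + t_ * step_b
    eta <- joint_eta(dat, beta, u)
    f <- f_new
    ridge <- 0
    d_current <- FALSE
    if (moved < 1e-11 * (1 + abs(f)) && it > 2) { conv <- TRUE; break }
  }
  # log-determinant over the *free* random effects with the true curvature
  logdet <- 0
  n_free <- sum(free)
  if (n_free > 0) {
    if (!d_current) {
      d <- fam_derivs(dat$fam, dat$y, dat$m, eta, phi)
      cvals <- pmax(-dat$w * d$d2, 0)
    }
    prec_eff <- ifelse(free, prec, 1e12)
    H <- assemble_H(dat, cvals, prec_eff)
    Chf <- tryCatch({
      if (is.null(Ch)) Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
      else Matrix::update(Ch, H)
    }, error = function(e) NULL)
    if (is.null(Chf)) return(list(ok = FALSE, f = f))
    Ch <- Chf
    ld_all <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
    # pinned (excluded) REs contribute log(1e12) each; subtract them off
    logdet <- ld_all - sum(!free) * log(1e12)
  }
  state$u <- u
  state$Ch <- Ch
  if (profile_beta) state$beta <- beta
  list(ok = TRUE, u = u, beta = beta, eta = eta, f = f, logdet = logdet,
       n_free = n_free, converged = conv, Ch = Ch, free = free, prec = prec)
}

laplace_value <- function(dat, sol, sd_vec) {
  # marginal log-likelihood: data + penalty at mode, prior normalizers for
  # the integrated-over components, minus half the log-determinant
  ll <- sol$f
  for (g in seq_along(dat$grp))
    if (sd_vec[g] > 1e-12) ll <- ll - dat$qs[g] * log(sd_vec[g])
  unname(ll - 0.5 * sol$logdet)
}

#' Laplace-approximated marginal log-likelihood
#'
#' Computes `log integral L(y | beta, u) p(u | sd) du` for fixed parameters
#' by the Laplace approximation: the mode of the joint penalized
#' log-likelihood over the stacked random-intercept vector is found by
#' damped Newton iterations, and the Gaussian integral uses the
#' log-determinant of the sparse negative Hessian at the mode (sparse
#' Cholesky). With all random-intercept SDs zero the integral is absent and
#' the value equals the fixed-effect GLM log-likelihood exactly.
#'
#' @param spec a [glmm_spec()].
#' @param data a data frame with the response, covariate, and grouping
#'   columns.
#' @param params a list with `beta` (fixed effects, intercept first),
#'   `sd` (named or positional SDs per grouping factor), and `phi`
#'   (beta-binomial dispersion; ignored otherwise).
#' @param weights optional non-negative case weights (replication counts).
#' @param control a [glmm_control()].
#' @return the marginal log-likelihood (scalar).
#' @export
laplace_loglik <- function(spec, data, params, weights = NULL,
                           control = glmm_control()) {
  dat <- prepare_glmm_data(spec, data, weights)
  dat$fam <- spec$family
  sd_vec <- resolve_sd(params$sd, dat)
  state <- new.env(parent = emptyenv())
  sol <- inner_newton(dat, resolve_beta(params$beta, dat), sd_vec,
                      params$phi %||% NULL, state, control)
  if (!sol$ok || !sol$converged)
    stop_ale("inner Newton did not converge (last objective %.6g)", sol$f,
             class = "alepanel_inner_nonconvergence")
  laplace_value(dat, sol, sd_vec)
}

resolve_sd <- function(sd, dat) {
  if (length(dat$grp) == 0) return(numeric(0))
  if (is.null(sd)) return(rep(0, length(dat$grp)))
  if (!is.null(names(sd)) && all(names(dat$grp) %in% names(sd)))
    sd <- sd[names(dat$grp)]
  if (length(sd) != length(dat$grp))
    stop_ale("need one SD per grouping factor")
  as.numeric(sd)
}

resolve_beta <- function(beta, dat) {
  if (length(beta) != dat$p)
    stop_ale("beta has length %d, expected %d", length(beta), dat$p)
  as.numeric(beta)
}

# ---- maximum-likelihood fit ------------------------------------------------

start_values <- function(dat, spec) {
  wsum <- sum(dat$w)
  if (spec$family == "poisson") {
    mu0 <- max(sum(dat$w * dat$y) / wsum, 1e-4)
    beta0 <- log(mu0)
    phi0 <- NULL
  } else {
    p0 <- min(max(sum(dat$w * dat$y) / sum(dat$w * dat$m), 1e-4), 1 - 1e-4)
    beta0 <- qlogis(p0)
    phi0 <- NULL
    if (spec$family == "betabinomial") {
      mbar <- sum(dat$w * dat$m) / wsum
      vb <- mbar * p0 * (1 - p0)
      vy <- sum(dat$w * (dat$y - mbar * p0)^2) / wsum
      r <- max(vy / vb, 1.01)
      phi0 <- min(max((mbar - r) / (r - 1), 0.5), 1e4)
    }
  }
  list(beta = c(beta0, rep(0, dat$p - 1)), sd = rep(0.3, length(dat$grp)),
       phi = phi0)
}

#' Fit a crossed random-intercept GLMM by Laplace-approximated ML
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects, the log random-intercept SDs, and (beta-binomial only) the log
#' dispersion. For speed, the fixed effects are first profiled into the
#' inner Newton solve while a quasi-Newton outer optimizer handles the
#' variance parameters; a final joint polish on the exact Laplace objective
#' then refines all parameters (disable via [glmm_control()]).
#'
#' Wald covariance for the fixed effects is conditional on the variance
#' parameters (Schur complement of the joint Hessian, as in lme4);
#' variance-parameter covariance comes from finite-difference curvature of
#' the profiled objective on the log scale. SD estimates at the lower
#' optimization bound are reported as converged-at-boundary (sigma
#' approximately 0), not as failures; any fixed effect beyond 15 on the link
#' scale triggers a separation/rare-event warning and is flagged.
#'
#' @inheritParams laplace_loglik
#' @param start optional list with `beta`, `sd`, `phi` starting values.
#' @param seed integer seed used only for jittered restarts.
#' @return an object of class `ale_glmm_fit` with components
#'   `coefficients` (link scale), `sd`, `phi`, `loglik`, `df`, `AIC`,
#'   `BIC`, `n_obs`, `vcov_fixed`, `convergence`, `boundary`, `flags`.
#' @export
fit_glmm <- function(spec, data, weights = NULL, start = NULL, seed = 1,
                     control = glmm_control()) {
  dat <- prepare_glmm_data(spec, data, weights)
  dat$fam <- spec$family
  st <- start_values(dat, spec)
  if (!is.null(start)) st[names(start)] <- start
  has_phi <- spec$family == "betabinomial"
  nG <- length(dat$grp)
  state <- new.env(parent = emptyenv())
  state$beta <- st$beta

  flags <- character(0)

  if (nG == 0 && !has_phi) {
    # plain GLM: inner Newton over beta alone is the exact MLE
    sol <- inner_newton(dat, st$beta, numeric(0), NULL, state, control,
                        profile_beta = TRUE)
    theta_hat <- numeric(0)
    beta_hat <- sol$beta
    phi_hat <- NULL
    ll <- sol$f
    status <- if (sol$converged) "converged" else "inner_nonconvergence"
  } else {
    # outer over (sd per group, log phi), beta profiled inside; the SD
    # scale (not log) lets boundary estimates land exactly on sigma = 0
    par0 <- c(st$sd, if (has_phi) log(st$phi))
    lower <- c(rep(0, nG), if (has_phi) -5)
    upper <- c(rep(150, nG), if (has_phi) control$phi_log_upper)
    split_par <- function(par) {
      list(sd = par[seq_len(nG)],
           phi = if (has_phi) exp(par[nG + 1]) else NULL)
    }
    obj <- function(par) {
      pp <- split_par(par)
      sol <- inner_newton(dat, state$beta, pp$sd, pp$phi, state, control,
                          profile_beta = TRUE)
      if (!sol$ok || !is.finite(sol$f)) return(1e10)
      -laplace_value(dat, sol, pp$sd)
    }
    run <- function(par_start) {
      nlminb(par_start, obj, lower = lower, upper = upper,
             control = list(rel.tol = control$rel_tol,
                            iter.max = control$max_iter,
                            eval.max = 10 * control$max_iter))
    }
    starts <- list(par0)
    if (has_phi && nG > 0 && is.null(start) && control$multistart) {
      # the beta-binomial surface has two canonical regimes: year-to-year
      # overdispersion (small sigma, moderate phi) and persistent entity
      # heterogeneity (sigma > 0, phi large); try both and keep the better
      starts <- c(starts, list(c(rep(0.5, nG), control$phi_log_upper)))
    }
    opts <- lapply(starts, run)
    opt <- opts[[which.min(vapply(opts, function(o)
      if (is.finite(o$objective)) o$objective else Inf, numeric(1)))]]
    tries <- 0
    set.seed(substream_seed(seed, "glmm_restarts"))
    while ((!is.finite(opt$objective) || opt$convergence != 0) &&
           tries < control$restarts) {
      tries <- tries + 1
      opt2 <- run(pmin(pmax(par0 + rnorm(length(par0), 0, 0.3), lower),
                       upper))
      if (is.finite(opt2$objective) &&
          (!is.finite(opt$objective) || opt2$objective <= opt$objective))
        opt <- opt2
      if (opt$convergence == 0) break
    }
    par_hat <- opt$par
    status <- if (opt$convergence == 0) "converged" else "outer_nonconvergence"

    if (control$polish) {
      # joint refinement of (beta, sd, log phi) on the exact Laplace
      # objective; starts at the profiled optimum, so this is cheap
      pb <- dat$p
      obj_full <- function(par) {
        beta <- par[seq_len(pb)]
        pp <- split_par(par[-seq_len(pb)])
        sol <- inner_newton(dat, beta, pp$sd, pp$phi, state, control)
        if (!sol$ok || !is.finite(sol$f)) return(1e10)
        -laplace_value(dat, sol, pp$sd)
      }
      optf <- nlminb(c(state$beta, par_hat), obj_full,
                     lower = c(rep(-Inf, pb), lower),
                     upper = c(rep(Inf, pb), upper),
                     control = list(rel.tol = control$rel_tol,
                                    iter.max = control$max_iter))
      if (is.finite(optf$objective) && optf$objective <= opt$objective + 1e-6) {
        state$beta <- optf$par[seq_len(pb)]
        par_hat <- optf$par[-seq_len(pb)]
        if (optf$convergence == 0) status <- "converged"
      }
    }
    beta_hat <- state$beta
    pp <- split_par(par_hat)
    sd_hat <- pp$sd
    phi_hat <- pp$phi
    sol <- inner_newton(dat, beta_hat, sd_hat, phi_hat, state, control)
    ll <- laplace_value(dat, sol, sd_hat)
    # stored representation: log SDs (floored at the boundary) and log phi
    theta_hat <- c(log(pmax(sd_hat, exp(control$sd_log_lower))),
                   if (has_phi) log(phi_hat))
  }

  sd_hat <- if (nG > 0) exp(theta_hat[seq_len(nG)]) else numeric(0)
  names(sd_hat) <- names(dat$grp)
  boundary <- nG > 0 & theta_hat[seq_len(nG)] <= control$sd_log_lower + 1e-6
  names(boundary) <- names(dat$grp)
  sd_hat[boundary] <- 0
  if (any(boundary)) {
    status <- paste0(status, "_at_boundary")
    flags <- c(flags, paste0("sd_", names(sd_hat)[boundary], "_boundary"))
  }
  if (has_phi && theta_hat[nG + 1] >= control$phi_log_upper - 1e-6)
    flags <- c(flags, "phi_upper_bound")
  names(beta_hat) <- colnames(dat$X)
  if (any(abs(beta_hat) > 15)) {
    flags <- c(flags, paste0("separation:",
                             names(beta_hat)[abs(beta_hat) > 15]))
    warning("possible separation / unreliable rare-event fit: |coefficient| > 15")
  }

  # Wald pieces
  d <- fam_derivs(spec$family, dat$y, dat$m, sol$eta, phi_hat)
  cvals <- pmax(-dat$w * d$d2, 0)
  Xc <- dat$X * cvals
  Hbb <- crossprod(dat$X, Xc)
  if (dat$q > 0 && sol$n_free > 0) {
    A <- matrix(0, dat$q, dat$p)
    for (g in seq_along(dat$grp))
      for (k in seq_len(dat$p))
        A[dat$offs[g] + seq_len(dat$qs[g]), k] <-
          group_sum(Xc[, k], dat$grp[[g]]$idx, dat$qs[g])
    Tm <- as.matrix(Matrix::solve(sol$Ch, A, system = "A"))
    S <- Hbb - crossprod(A, Tm)
  } else S <- Hbb
  vcov_fixed <- tryCatch(solve(S), error = function(e) matrix(NA, dat$p, dat$p))
  dimnames(vcov_fixed) <- list(names(beta_hat), names(beta_hat))

  df <- dat$p + nG + as.integer(has_phi)
  fit <- structure(list(
    spec = spec, family = spec$family,
    coefficients = beta_hat, sd = sd_hat, phi = phi_hat,
    loglik = ll, df = df,
    AIC = -2 * ll + 2 * df,
    BIC = -2 * ll + df * log(dat$n_obs),
    n_obs = dat$n_obs,
    n_groups = setNames(dat$qs, names(dat$grp)),
    vcov_fixed = vcov_fixed,
    se_fixed = sqrt(pmax(diag(vcov_fixed), 0)),
    theta = theta_hat, convergence = status, boundary = boundary,
    flags = flags, control = control),
    class = "ale_glmm_fit")
  # kept for profile intervals, decomposition, and refits
  fit$internals <- list(dat = dat, state = state, eta = sol$eta)

  n_par <- dat$p + length(theta_hat)
  if ((nG > 0 || has_phi) && n_par <= control$full_vcov_max &&
      !any(boundary)) {
    # small interior models: full observed information over (beta, theta),
    # so fixed-effect intervals carry the variance-parameter uncertainty
    vc <- full_vcov(fit)
    if (!anyNA(vc)) {
      fit$vcov_fixed <- vc[seq_len(dat$p), seq_len(dat$p), drop = FALSE]
      dimnames(fit$vcov_fixed) <- list(names(beta_hat), names(beta_hat))
      fit$se_fixed <- sqrt(pmax(diag(fit$vcov_fixed), 0))
      names(fit$se_fixed) <- names(beta_hat)
      fit$vcov_theta <- vc[-seq_len(dat$p), -seq_len(dat$p), drop = FALSE]
    } else if (nG > 0 || has_phi) fit$vcov_theta <- theta_vcov(fit)
  } else if (nG > 0 || has_phi) {
    # larger models: conditional fixed-effect covariance (Schur block) and
    # profiled variance-parameter curvature, as in lme4
    fit$vcov_theta <- theta_vcov(fit)
  }
  fit
}

# finite-difference observed information of the exact Laplace objective
# over the joint parameter (beta, log sd, log phi)
full_vcov <- function(fit) {
  dat <- fit$internals$dat
  control <- fit$control
  nG <- length(dat$grp)
  has_phi <- fit$family == "betabinomial"
  par <- c(fit$coefficients, fit$theta)
  state <- new.env(parent = emptyenv())
  state$u <- fit$internals$state$u
  f <- function(p_) {
    beta <- p_[seq_len(dat$p)]
    th <- p_[-seq_len(dat$p)]
    sdv <- if (nG) exp(th[seq_len(nG)]) else numeric(0)
    phi <- if (has_phi) exp(th[length(th)]) else NULL
    sol <- inner_newton(dat, beta, sdv, phi, state, control)
    if (!sol$ok) return(NA_real_)
    laplace_value(dat, sol, sdv)
  }
  k <- length(par)
  h <- 0.02
  Hm <- matrix(NA_real_, k, k)
  f0 <- f(par)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
    if (i == j) {
      Hm[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / h^2
    } else {
      Hm[i, j] <- Hm[j, i] <-
        (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) +
           f(par - ei - ej)) / (4 * h^2)
    }
  }
  tryCatch(solve(-Hm), error = function(e) matrix(NA_real_, k, k))
}

theta_vcov <- function(fit) {
  dat <- fit$internals$dat
  control <- fit$control
  nG <- length(dat$grp)
  has_phi <- fit$family == "betabinomial"
  th <- fit$theta
  state <- new.env(parent = emptyenv())
  state$beta <- fit$coefficients
  state$u <- fit$internals$state$u
  f <- function(t_) {
    sdv <- exp(t_[seq_len(nG)])
    phi <- if (has_phi) exp(t_[nG + 1]) else NULL
    sol <- inner_newton(dat, state$beta, sdv, phi, state, control,
                        profile_beta = TRUE)
    if (!sol$ok) return(NA_real_)
    laplace_value(dat, sol, sdv)
  }
  k <- length(th)
  h <- 0.02
  Hm <- matrix(NA_real_, k, k)
  f0 <- f(th)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
    if (i == j) {
      Hm[i, i] <- (f(th + ei) - 2 * f0 + f(th - ei)) / h^2
    } else {
      Hm[i, j] <- Hm[j, i] <-
        (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) +
           f(th - ei - ej)) / (4 * h^2)
    }
  }
  tryCatch(solve(-Hm), error = function(e) matrix(NA_real_, k, k))
}
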