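#' Gauss-Hermite nodes and weights (Golub-Welsch)
#'
#' Physicists' convention: approximates `integral h(z) exp(-z^2) dz` by
#' `sum(w * h(x))`. Computed from the eigen-decomposition of the Jacobi
#' matrix; intended for the quadrature reference below.
#'
#' @param n number of nodes.
#' @return list with `x` (nodes) and `w` (weights).
#' @export
gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ord]^2) * sqrt(pi))
}

#' Dense adaptive Gauss-Hermite marginal log-likelihood (reference)
#'
#' Validation-grade evaluation of the marginal likelihood by full tensor
#' adaptive Gauss-Hermite quadrature over the *entire* stacked
#' random-effect vector (not per group), feasible only for a handful of
#' random-effect levels. The integrand's mode and curvature are obtained
#' independently of the production Laplace path (dense `stats::optim`
#' BFGS with numerical derivatives), the grid is recentred and rescaled by
#' the Cholesky factor of the dense negative Hessian, and the sum is
#' accumulated in log space. Used to validate [laplace_loglik()] on tiny
#' crossed fixtures.
#'
#' @inheritParams laplace_loglik
#' @param nodes quadrature nodes per dimension.
#' @param max_points cap on the tensor grid size.
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik_quadrature <- function(spec, data, params, weights = NULL,
                                       nodes = 15, max_points = 2e6) {
  dat <- prepare_glmm_data(spec, data, weights)
  dat$fam <- spec$family
  sd_vec <- resolve_sd(params$sd, dat)
  beta <- resolve_beta(params$beta, dat)
  phi <- params$phi %||% NULL
  active <- which(rep(sd_vec, dat$qs) > 1e-12)
  q <- length(active)
  xb <- as.vector(dat$X %*% beta)
  prec_full <- rep(ifelse(sd_vec > 1e-12, 1 / sd_vec^2, Inf), dat$qs)
  eta_of <- function(u_active) {
    u <- numeric(dat$q)
    u[active] <- u_active
    eta <- xb
    for (g in seq_along(dat$grp))
      eta <- eta + u[dat$offs[g] + dat$grp[[g]]$idx]
    eta
  }
  logprior_const <- -sum(dat$qs[sd_vec > 1e-12] * log(sd_vec[sd_vec > 1e-12])) -
    q / 2 * log(2 * pi)
  gfun <- function(u_active) {
    d <- fam_derivs(dat$fam, dat$y, dat$m, eta_of(u_active), phi, deriv = 0L)
    sum(dat$w * d$ll) - 0.5 * sum(u_active^2 * prec_full[active]) +
      logprior_const
  }
  if (q == 0) return(gfun(numeric(0)))
  if (nodes^q > max_points)
    stop_ale("tensor grid too large (%d^%d points); reference is for tiny fixtures",
             nodes, q)
  opt <- optim(numeric(q), function(u) -gfun(u), method = "BFGS",
               hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  m <- opt$par
  H <- (opt$hessian + t(opt$hessian)) / 2
  R <- chol(H)
  gh <- gauss_hermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), q)))
  Z <- matrix(gh$x[grid], ncol = q)
  logw <- rowSums(matrix(log(gh$w[grid]), ncol = q))
  # u = m + sqrt(2) R^-1 z ; du = 2^(q/2) / det(R) dz
  U <- t(m + sqrt(2) * backsolve(R, t(Z)))
  chunk <- max(1L, floor(5e6 / max(dat$n_rows, 1)))
  vals <- numeric(nrow(U))
  for (s in seq(1, nrow(U), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(U))
    vals[idx] <- vapply(idx, function(i) gfun(U[i, ]), numeric(1))
  }
  logsumexp(vals + rowSums(Z^2) + logw) +
    q / 2 * log(2) - sum(log(diag(R)))
}
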