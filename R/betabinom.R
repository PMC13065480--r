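#' Beta-binomial distribution (Morris mean/dispersion parameterization)
#'
#' Success probability drawn from Beta(alpha, beta) with `mu =
#' alpha/(alpha+beta)` and `phi = alpha+beta`; the count variance over `n`
#' trials is `mu(1-mu) * n(phi+n)/(phi+1)`, always at least the binomial
#' variance.
#'
#' @param x count(s).
#' @param size number of trials.
#' @param mu mean success probability in (0, 1).
#' @param phi dispersion (alpha + beta), > 0; larger means closer to
#'   binomial.
#' @param log return log probabilities.
#' @return `dbetabinom`: probabilities; `rbetabinom`: random counts.
#' @export
dbetabinom <- function(x, size, mu, phi, log = FALSE) {
  a <- mu * phi; b <- (1 - mu) * phi
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

#' @rdname dbetabinom
#' @param n number of draws.
#' @export
rbetabinom <- function(n, size, mu, phi) {
  p <- rbeta(n, mu * phi, (1 - mu) * phi)
  rbinom(n, size, p)
}

#' Map a Polya urn to its beta-binomial law
#'
#' Cumulative blue-draw totals of a Polya urn with `white` w, `blue` b, and
#' per-draw reinforcement `c > 0` are exactly beta-binomial with shape
#' parameters `alpha = b/c` and `beta = w/c`; the induced mean is
#' `mu = alpha/(alpha+beta) = b/(w+b)` and the dispersion
#' `phi = alpha+beta = (w+b)/c`.
#'
#' @param spec an [urn_spec()] with `reinforcement > 0`.
#' @return list with `alpha`, `beta`, `mu`, `phi`, `trials`
#'   (`draws_per_year`).
#' @export
urn_to_betabinom <- function(spec) {
  stopifnot(inherits(spec, "urn_spec"))
  if (spec$reinforcement == 0)
    stop_ale("no reinforcement (c = 0): totals are binomial, not beta-binomial")
  alpha <- spec$blue / spec$reinforcement
  beta <- spec$white / spec$reinforcement
  list(alpha = alpha, beta = beta,
       mu = alpha / (alpha + beta), phi = alpha + beta,
       trials = spec$draws_per_year)
}

#' Inverse mapping: beta-binomial shapes to an urn at a given reinforcement
#'
#' @param alpha,beta beta shape parameters.
#' @param reinforcement balls added per draw (defaults to 1).
#' @param draws_per_year event slots per year.
#' @return an [urn_spec()] with `blue = alpha * c`, `white = beta * c`.
#' @export
betabinom_to_urn <- function(alpha, beta, reinforcement = 1,
                             draws_per_year = 1) {
  urn_spec(white = beta * reinforcement, blue = alpha * reinforcement,
           reinforcement = reinforcement, draws_per_year = draws_per_year)
}

#' Beta-binomial count variance
#'
#' `V = mu (1 - mu) * n (phi + n) / (phi + 1)` for `n` trials.
#'
#' @param mu mean probability.
#' @param phi dispersion.
#' @param trials number of trials n.
#' @return the variance.
#' @export
betabinom_variance <- function(mu, phi, trials) {
  mu * (1 - mu) * trials * (phi + trials) / (phi + 1)
}
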