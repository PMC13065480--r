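#' @keywords internal
"_PACKAGE"

#' @importFrom stats dpois rpois rnorm runif rbinom rbeta plogis qlogis
#'   optim nlminb uniroot qchisq qnorm pnorm sd var median aggregate
#'   complete.cases setNames lm coef pchisq
#' @importFrom utils head tail read.csv write.csv
NULL

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Derive a reproducible sub-seed from a base seed
#'
#' All generators in the package draw their randomness from a single integer
#' seed. Named sub-streams (one per pipeline stage) are derived with a fixed
#' integer hash so that stages are independent yet fully determined by the
#' one seed. Results stay below 2^31.
#'
#' @param seed integer base seed.
#' @param stream character stream label.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ale <- function(fmt, ..., class = "alepanel_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
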