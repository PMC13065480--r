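# shared fixtures and independent oracles

# small event panel built by hand (no generators)
toy_event_panel <- function(catalog = ale_catalog(c("A", "B"))) {
  ale_panel(tibble::tibble(
    id = c(1, 1, 2, 2), hh_id = c(1, 1, 2, 2),
    year = c(2001, 2002, 2001, 2002), age = c(30, 31, 50, 51),
    A = c(1L, 0L, 1L, 0L), B = c(1L, 0L, 0L, 0L)),
    catalog = catalog)
}

write_panel_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# O(n p^2) brute-force joint/conditional tally, independent of the package
# implementation (plain loops over rows)
brute_joint_cond <- function(m) {
  p <- ncol(m)
  joint <- matrix(NA_real_, p, p); cond <- joint
  for (a in 1:p) for (b in 1:p) {
    num <- 0; na <- 0; nb <- 0; nobs <- 0
    for (r in 1:nrow(m)) {
      if (is.na(m[r, a]) || is.na(m[r, b])) next
      nobs <- nobs + 1
      if (m[r, a] == 1 && m[r, b] == 1) num <- num + 1
      if (m[r, a] == 1) na <- na + 1
    }
    joint[a, b] <- num / nobs
    cond[a, b] <- if (na > 0) num / na else NA_real_
  }
  dimnames(joint) <- dimnames(cond) <- list(colnames(m), colnames(m))
  list(joint = joint, conditional = cond)
}

# tiny crossed Poisson fixture for the quadrature comparisons:
# 3 individuals in 2 households, 3 years each -> 5 random effects
tiny_crossed_data <- function(seed = 42) {
  set.seed(seed)
  df <- expand.grid(individual = 1:3, year = 1:3)
  df$household <- c(1, 2, 1)[df$individual]
  df$y <- rpois(nrow(df), exp(0.2 + 0.3 * rnorm(3)[df$individual]))
  df
}

# discrete power-law sampler by inverse CDF on a finite grid
sample_powerlaw <- function(n, exponent, xmax = 1e5, seed = 1) {
  set.seed(seed)
  xs <- seq_len(xmax)
  pm <- xs^(-exponent); pm <- pm / sum(pm)
  sample(xs, n, replace = TRUE, prob = pm)
}
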