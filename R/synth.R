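#' Polya urn specification
#'
#' Each person owns an urn with `white` no-event balls and `blue` event
#' balls; every year `draws_per_year` balls are drawn one at a time, each
#' returned together with `reinforcement` extra balls of its own colour
#' (reinforcement happens after every single draw, and the urn state
#' persists across years). The initial per-draw event risk is
#' `blue / (white + blue)`.
#'
#' @param white initial number of white (no-event) balls, > 0.
#' @param blue initial number of blue (event) balls, > 0.
#' @param reinforcement balls added per draw, >= 0 (`0` removes the
#'   self-reinforcement and the yearly counts become plain binomial).
#' @param draws_per_year number of draws (event slots) per year, >= 1.
#' @return an object of class `urn_spec`.
#' @export
urn_spec <- function(white, blue, reinforcement, draws_per_year) {
  stopifnot(white > 0, blue > 0, reinforcement >= 0, draws_per_year >= 1)
  structure(list(white = white, blue = blue, reinforcement = reinforcement,
                 draws_per_year = as.integer(draws_per_year)),
            class = "urn_spec")
}

#' Frailty parameters
#'
#' @param rate mean yearly event rate on the natural scale, > 0.
#' @param sd_individual SD of the individual log-normal random intercept.
#' @param sd_household SD of the household log-normal random intercept.
#' @return an object of class `frailty_params`.
#' @export
frailty_params <- function(rate, sd_individual = 0, sd_household = 0) {
  stopifnot(rate > 0, sd_individual >= 0, sd_household >= 0)
  structure(list(rate = rate, sd_individual = sd_individual,
                 sd_household = sd_household), class = "frailty_params")
}

#' Random individual-to-household assignment
#'
#' Assigns `n_individuals` to `n_households` so that every household is
#' non-empty; remaining individuals are allocated uniformly at random.
#'
#' @param n_individuals,n_households sizes (`n_households <=
#'   n_individuals`).
#' @param seed integer seed.
#' @return a tibble `id`, `hh_id`.
#' @export
make_household_map <- function(n_individuals, n_households, seed = 1) {
  stopifnot(n_households <= n_individuals)
  set.seed(substream_seed(seed, "households"))
  hh <- c(seq_len(n_households),
          sample.int(n_households, n_individuals - n_households,
                     replace = TRUE))
  tibble::tibble(id = seq_len(n_individuals), hh_id = hh)
}

synth_ages <- function(n_individuals, n_years, seed, age_range = c(18L, 70L)) {
  set.seed(substream_seed(seed, "ages"))
  age0 <- sample(seq(age_range[1], age_range[2]), n_individuals,
                 replace = TRUE)
  outer(age0, 0:(n_years - 1), `+`) # n x T, row i = individual i's ages
}

count_panel <- function(counts, hh_map, ages, seed, start_year, provenance) {
  n <- nrow(hh_map); T_ <- ncol(ages)
  ale_panel(
    tibble::tibble(
      id = rep(hh_map$id, each = T_),
      hh_id = rep(hh_map$hh_id, each = T_),
      year = rep(start_year + 0:(T_ - 1), times = n),
      age = as.integer(t(ages))[seq_len(n * T_)],
      count = counts),
    catalog = NULL, provenance = provenance, validate = FALSE)
}

#' Simulate a homogeneous-Poisson ("bad luck") count panel
#'
#' Yearly counts are i.i.d. Poisson(`rate`) across individuals and years:
#' risk is static and identical for everyone, so any apparent clustering is
#' chance. Draws are laid out individual-major, so panels that differ only
#' in `n_individuals` share the draws of their common individuals.
#'
#' @param rate yearly event rate, > 0.
#' @param n_individuals,n_years panel dimensions.
#' @param seed integer seed.
#' @param start_year first calendar year.
#' @return a count `ale_panel` (each individual is their own household).
#' @export
simulate_poisson_panel <- function(rate, n_individuals, n_years, seed,
                                   start_year = 2001L) {
  if (rate <= 0) stop_ale("rate must be > 0")
  ages <- synth_ages(n_individuals, n_years, seed)
  set.seed(substream_seed(seed, "poisson_counts"))
  counts <- rpois(n_individuals * n_years, rate) # individual-major
  count_panel(counts, tibble::tibble(id = seq_len(n_individuals),
                                     hh_id = seq_len(n_individuals)),
              ages, seed, start_year,
              sprintf("simulate_poisson_panel(rate=%g, n=%d, T=%d, seed=%d)",
                      rate, n_individuals, n_years, seed))
}

#' Simulate a crossed-frailty count panel
#'
#' Each individual i in household h has log-rate
#' `log(rate) + u_i + v_h` with `u_i ~ N(0, sd_individual^2)` and
#' `v_h ~ N(0, sd_household^2)`; conditional on the frailties, yearly counts
#' are independent Poisson. With both SDs zero this reduces exactly to the
#' homogeneous Poisson process.
#'
#' @param params a [frailty_params()].
#' @param household_map a data frame `id`, `hh_id` covering every
#'   individual, e.g. from [make_household_map()].
#' @param n_years number of years.
#' @param seed integer seed.
#' @param start_year first calendar year.
#' @return a count `ale_panel`.
#' @export
simulate_frailty_panel <- function(params, household_map, n_years, seed,
                                   start_year = 2001L) {
  stopifnot(inherits(params, "frailty_params"))
  hh_map <- tibble::as_tibble(household_map)
  if (anyNA(hh_map$hh_id)) stop_ale("every individual needs a household")
  n <- nrow(hh_map)
  hh_levels <- sort(unique(hh_map$hh_id))
  set.seed(substream_seed(seed, "frailty_u"))
  u <- rnorm(n, 0, params$sd_individual)
  set.seed(substream_seed(seed, "frailty_v"))
  v <- rnorm(length(hh_levels), 0, params$sd_household)
  rate_i <- params$rate * exp(u + v[match(hh_map$hh_id, hh_levels)])
  ages <- synth_ages(n, n_years, seed)
  set.seed(substream_seed(seed, "frailty_counts"))
  counts <- rpois(n * n_years, rep(rate_i, each = n_years))
  count_panel(counts, hh_map, ages, seed, start_year,
              sprintf(paste0("simulate_frailty_panel(rate=%g, sd_i=%g, ",
                             "sd_h=%g, n=%d, T=%d, seed=%d)"),
                      params$rate, params$sd_individual, params$sd_household,
                      n, n_years, seed))
}

#' Simulate a self-reinforcing Polya-urn count panel
#'
#' Literal urn semantics: per individual, `draws_per_year` sequential draws
#' per year for `n_years`; after each draw the drawn colour is reinforced
#' with `reinforcement` balls; the yearly count is the number of blue
#' (event) draws; the urn state carries over across years. By
#' exchangeability, the cumulative count after m draws is exactly
#' BetaBinomial(m, blue/c, white/c) when `reinforcement = c > 0`.
#'
#' @param spec an [urn_spec()].
#' @param n_individuals,n_years panel dimensions.
#' @param seed integer seed.
#' @param heterogeneity optional list with `sd_individual` and/or
#'   `sd_household`: log-normal multiplicative perturbations of each urn's
#'   initial blue-ball count, shared within households for the household
#'   component (requires `household_map`).
#' @param household_map optional data frame `id`, `hh_id`; defaults to one
#'   household per individual.
#' @param start_year first calendar year.
#' @return a count `ale_panel`.
#' @export
simulate_urn_panel <- function(spec, n_individuals, n_years, seed,
                               heterogeneity = NULL, household_map = NULL,
                               start_year = 2001L) {
  stopifnot(inherits(spec, "urn_spec"))
  n <- n_individuals
  hh_map <- if (is.null(household_map))
    tibble::tibble(id = seq_len(n), hh_id = seq_len(n))
  else tibble::as_tibble(household_map)
  b0 <- rep(spec$blue, n)
  if (!is.null(heterogeneity)) {
    sdi <- heterogeneity$sd_individual %||% 0
    sdh <- heterogeneity$sd_household %||% 0
    set.seed(substream_seed(seed, "urn_het_i"))
    zi <- rnorm(n, 0, sdi)
    hh_levels <- sort(unique(hh_map$hh_id))
    set.seed(substream_seed(seed, "urn_het_h"))
    zh <- rnorm(length(hh_levels), 0, sdh)
    b0 <- b0 * exp(zi + zh[match(hh_map$hh_id, hh_levels)])
  }
  k <- spec$draws_per_year
  D <- k * n_years
  set.seed(substream_seed(seed, "urn_draws"))
  U <- matrix(runif(n * D), nrow = D) # column i = individual i's draws
  w <- rep(spec$white, n); b <- b0
  counts <- matrix(0L, nrow = n_years, ncol = n)
  cc <- spec$reinforcement
  for (d in seq_len(D)) {
    hit <- U[d, ] < b / (w + b)
    b <- b + cc * hit
    w <- w + cc * (!hit)
    yr <- ((d - 1L) %/% k) + 1L
    counts[yr, ] <- counts[yr, ] + hit
  }
  ages <- synth_ages(n, n_years, seed)
  count_panel(as.integer(counts), hh_map, ages, seed, start_year,
              sprintf(paste0("simulate_urn_panel(w=%g, b=%g, c=%g, k=%d, ",
                             "n=%d, T=%d, seed=%d)"),
                      spec$white, spec$blue, cc, k, n, n_years, seed))
}

#' Simulate yearly counts with lag-1 autocorrelation
#'
#' Log-linear count autoregression: given last year's count `y[t-1]` and
#' the entity effects, `y[t] ~ Poisson(exp(log(rate) + log(lag_rr) *
#' y[t-1] + u_i + v_h))`, truncated at `max_count` (the instrument records
#' at most that many events per year; truncation also keeps the positive
#' feedback stable). The first year draws from the process without a lag
#' term. This is the data-generating structure the count autocorrelation
#' model estimates.
#'
#' @param rate baseline yearly rate, > 0.
#' @param lag_rr rate ratio per additional prior-year event (natural
#'   scale), > 0.
#' @param sd_individual,sd_household SDs of the log-scale random
#'   intercepts.
#' @param household_map data frame `id`, `hh_id` covering every individual.
#' @param n_years number of years.
#' @param seed integer seed.
#' @param max_count yearly count cap (defaults to 12 event slots).
#' @param start_year first calendar year.
#' @return a count `ale_panel`.
#' @export
simulate_count_ar_panel <- function(rate, lag_rr, sd_individual = 0,
                                    sd_household = 0, household_map,
                                    n_years, seed, max_count = 12L,
                                    start_year = 2001L) {
  stopifnot(rate > 0, lag_rr > 0)
  hh_map <- tibble::as_tibble(household_map)
  n <- nrow(hh_map)
  hh_levels <- sort(unique(hh_map$hh_id))
  set.seed(substream_seed(seed, "ar_u"))
  u <- rnorm(n, 0, sd_individual)
  set.seed(substream_seed(seed, "ar_v"))
  v <- rnorm(length(hh_levels), 0, sd_household)
  re <- u + v[match(hh_map$hh_id, hh_levels)]
  set.seed(substream_seed(seed, "ar_counts"))
  y <- matrix(0L, n, n_years)
  y[, 1] <- pmin(rpois(n, exp(log(rate) + re)), max_count)
  for (t in seq_len(n_years)[-1])
    y[, t] <- pmin(rpois(n, exp(log(rate) + log(lag_rr) * y[, t - 1] + re)),
                   max_count)
  ages <- synth_ages(n, n_years, seed)
  count_panel(as.integer(t(y)), hh_map, ages, seed, start_year,
              sprintf(paste0("simulate_count_ar_panel(rate=%g, lag_rr=%g, ",
                             "sd_i=%g, sd_h=%g, n=%d, T=%d, seed=%d)"),
                      rate, lag_rr, sd_individual, sd_household, n, n_years,
                      seed))
}

#' Cross-event dependence specification
#'
#' Target structure for the binary-event generator: per-event base logits,
#' within-year cross-event log-odds-ratios, lag-1 log-odds-ratios, and
#' shared entity random intercepts added to every event's logit.
#' Exclusivity-group members are sampled jointly as one categorical slot, so
#' within-group contemporaneous entries are structurally void and ignored.
#'
#' @param catalog an [ale_catalog()].
#' @param base_logits numeric vector, one per catalog event (recycled if
#'   length 1).
#' @param lor_contemp,lor_lag p x p matrices of log-odds-ratios
#'   (`[predictor, outcome]`); `NULL` means all zero.
#' @param sd_individual,sd_household SDs of the shared logit-scale random
#'   intercepts.
#' @return an object of class `ale_association`.
#' @export
ale_association <- function(catalog, base_logits,
                            lor_contemp = NULL, lor_lag = NULL,
                            sd_individual = 0, sd_household = 0) {
  p <- length(catalog$events)
  base_logits <- rep_len(base_logits, p)
  names(base_logits) <- catalog$events
  chk <- function(m, what) {
    if (is.null(m)) m <- matrix(0, p, p)
    if (!is.matrix(m) || any(dim(m) != p))
      stop_ale("%s matrix must be %d x %d", what, p, p)
    dimnames(m) <- list(catalog$events, catalog$events)
    m
  }
  structure(list(catalog = catalog, base_logits = base_logits,
                 lor_contemp = chk(lor_contemp, "contemporaneous"),
                 lor_lag = chk(lor_lag, "lag-1"),
                 sd_individual = sd_individual,
                 sd_household = sd_household),
            class = "ale_association")
}

#' Simulate a binary event panel with planted dependence
#'
#' Events are generated year by year via sequential conditional sampling in
#' catalog order: each event's logit is its base logit, plus the specified
#' contemporaneous log-ORs times the events already sampled this year, plus
#' the lag-1 log-ORs times last year's full event vector, plus the entity
#' random intercepts. An exclusivity group is sampled as a single
#' categorical slot (each member's probability `exp(eta_m)` against a
#' shared "no event" weight of 1), so members can never co-occur.
#'
#' @param assoc an [ale_association()].
#' @param n_individuals,n_years panel dimensions.
#' @param seed integer seed.
#' @param household_map optional data frame `id`, `hh_id`; defaults to one
#'   household per individual.
#' @param start_year first calendar year.
#' @param age_range inclusive range baseline ages are drawn from.
#' @return an event `ale_panel`.
#' @export
simulate_typed_panel <- function(assoc, n_individuals, n_years, seed,
                                 household_map = NULL, start_year = 2001L,
                                 age_range = c(18L, 70L)) {
  stopifnot(inherits(assoc, "ale_association"))
  catalog <- assoc$catalog
  p <- length(catalog$events)
  n <- n_individuals
  hh_map <- if (is.null(household_map))
    tibble::tibble(id = seq_len(n), hh_id = seq_len(n))
  else tibble::as_tibble(household_map)
  hh_levels <- sort(unique(hh_map$hh_id))
  set.seed(substream_seed(seed, "typed_u"))
  u <- rnorm(n, 0, assoc$sd_individual)
  set.seed(substream_seed(seed, "typed_v"))
  v <- rnorm(length(hh_levels), 0, assoc$sd_household)
  re <- u + v[match(hh_map$hh_id, hh_levels)]
  slots <- catalog_slots(catalog)
  ages <- synth_ages(n, n_years, seed, age_range)
  set.seed(substream_seed(seed, "typed_events"))
  y_prev <- matrix(0L, n, p, dimnames = list(NULL, catalog$events))
  out <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    y <- matrix(0L, n, p, dimnames = list(NULL, catalog$events))
    done <- character(0)
    for (slot in slots) {
      eta <- sapply(slot, function(e) {
        lp <- assoc$base_logits[[e]] + re
        if (length(done))
          lp <- lp + as.matrix(y[, done, drop = FALSE]) %*%
            assoc$lor_contemp[done, e]
        lp + y_prev %*% assoc$lor_lag[, e]
      })
      eta <- matrix(eta, nrow = n)
      if (length(slot) == 1L) {
        y[, slot] <- as.integer(runif(n) < plogis(eta[, 1]))
      } else {
        wts <- exp(eta)
        denom <- 1 + rowSums(wts)
        cum <- wts[, 1] / denom
        draw <- runif(n)
        pick <- integer(n) # 0 = none
        hitd <- draw < cum
        pick[hitd] <- 1L
        for (mi in seq_along(slot)[-1]) {
          newcum <- cum + wts[, mi] / denom
          sel <- draw >= cum & draw < newcum
          pick[sel] <- mi
          cum <- newcum
        }
        for (mi in seq_along(slot)) y[pick == mi, slot[mi]] <- 1L
      }
      done <- c(done, slot)
    }
    out[[t]] <- y
    y_prev <- y
  }
  rows <- do.call(rbind, lapply(seq_len(n_years), function(t) {
    cbind(id = seq_len(n), hh_id = hh_map$hh_id,
          year = start_year + t - 1L, age = ages[, t], out[[t]])
  }))
  rows <- tibble::as_tibble(as.data.frame(rows))
  rows <- rows[order(rows$id, rows$year), ]
  ale_panel(rows, catalog = catalog,
            provenance = sprintf("simulate_typed_panel(n=%d, T=%d, seed=%d)",
                                 n, n_years, seed),
            validate = FALSE)
}

#' Mask event cells and whole person-years at random
#'
#' @param panel an event `ale_panel`.
#' @param cell_rate probability of masking each event cell, in `[0, 1)`.
#' @param full_row_rate probability of masking all events of a person-year,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @return the panel with masked cells set to `NA`.
#' @export
inject_missingness <- function(panel, cell_rate = 0, full_row_rate = 0,
                               seed = 1) {
  stopifnot(cell_rate >= 0, cell_rate < 1, full_row_rate >= 0,
            full_row_rate < 1)
  if (cell_rate == 0 && full_row_rate == 0) return(panel)
  cat <- panel_catalog(panel)
  m <- events_matrix(panel)
  set.seed(substream_seed(seed, "missingness"))
  row_mask <- runif(nrow(m)) < full_row_rate
  cell_mask <- matrix(runif(length(m)) < cell_rate, nrow = nrow(m))
  m[cell_mask | row_mask] <- NA_integer_
  out <- panel
  out[cat$events] <- as.data.frame(m)
  restore_panel(out, panel)
}
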