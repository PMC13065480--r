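test_that("homogeneous Poisson panels have the requested rate and no overdispersion", {
  pan <- simulate_poisson_panel(0.96, 1370, 20, seed = 1)
  y <- yearly_counts(pan)
  expect_equal(length(y), 27400)
  expect_lt(abs(mean(y) - 0.96), 0.02)      # CLT bound at n = 27,400
  expect_lt(abs(var(y) / mean(y) - 1), 0.05) # equidispersion index
  expect_error(simulate_poisson_panel(0, 10, 2, seed = 1), "rate")
  # tiny rate limit: essentially all-zero panel
  pan0 <- simulate_poisson_panel(1e-6, 200, 5, seed = 1)
  expect_lte(sum(yearly_counts(pan0)), 1)
  # bit-reproducibility and individual-major prefix sharing
  expect_identical(as.data.frame(simulate_poisson_panel(0.5, 50, 4, seed = 9)),
                   as.data.frame(simulate_poisson_panel(0.5, 50, 4, seed = 9)))
  big <- simulate_poisson_panel(0.5, 80, 4, seed = 9)
  small <- simulate_poisson_panel(0.5, 50, 4, seed = 9)
  expect_identical(big$count[big$id <= 50], small$count)
})

test_that("frailty panels match the log-normal mixture moments", {
  # degenerate frailty reduces to homogeneous Poisson moments
  hh <- make_household_map(2000, 800, seed = 2)
  pan0 <- simulate_frailty_panel(frailty_params(0.8, 0, 0), hh, 10, seed = 2)
  y0 <- yearly_counts(pan0)
  expect_lt(abs(mean(y0) - 0.8), 0.03)
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.05)
  # marginal mean of the mixture is rate * exp((sd_i^2 + sd_h^2) / 2)
  pan <- simulate_frailty_panel(frailty_params(0.86, 0.34, 0.36), hh, 10,
                                seed = 3)
  y <- yearly_counts(pan)
  expect_lt(abs(mean(y) - 0.86 * exp((0.34^2 + 0.36^2) / 2)), 0.05)
  expect_gt(var(y) / mean(y), 1.1) # overdispersed whenever sigma > 0
  expect_error(simulate_frailty_panel(
    frailty_params(0.5), data.frame(id = 1, hh_id = NA), 2, seed = 1),
    "household")
})

test_that("urn panels without reinforcement are plain binomial", {
  us <- urn_spec(6, 2, 0, 6)
  pan <- simulate_urn_panel(us, 4000, 5, seed = 4)
  y <- yearly_counts(pan)
  p <- 2 / 8
  expect_lt(abs(mean(y) - 6 * p), 0.03)
  expect_lt(abs(var(y) - 6 * p * (1 - p)), 0.05)
  # single draw from a balanced urn: event probability one half
  one <- simulate_urn_panel(urn_spec(1, 1, 1, 1), 10000, 1, seed = 5)
  expect_lt(abs(mean(yearly_counts(one)) - 0.5), 0.02)
})

test_that("urn totals over a short prefix follow the exact beta-binomial law", {
  # m = 10 draws (k = 2 per year, 5 years); totals ~ BetaBinomial(10, b/c, w/c)
  us <- urn_spec(3, 1, 1, 2)
  pan <- simulate_urn_panel(us, 20000, 5, seed = 6)
  cum <- count_summaries(pan)$cumulative$total
  bb <- urn_to_betabinom(us)
  expected <- 20000 * dbetabinom(0:10, 10, bb$mu, bb$phi)
  observed <- tabulate(cum + 1, 11)
  chi <- sum((observed - expected)^2 / expected)
  p <- pchisq(chi, df = 10, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("typed panels honour base rates, independence, and exclusivity", {
  cat5 <- ale_catalog(paste0("e", 1:5),
                      exclusivity_groups = list(c("e2", "e3")))
  assoc <- ale_association(cat5, base_logits = qlogis(0.06))
  pan <- simulate_typed_panel(assoc, 2000, 10, seed = 7)
  m <- as.matrix(pan[cat5$events])
  # exclusivity is structural: group members never co-occur, any seed
  expect_equal(max(m[, "e2"] + m[, "e3"]), 1)
  # base rates recovered at sigma = 0 (binomial tolerance at n = 20,000)
  expect_lt(abs(mean(m[, "e1"]) - 0.06), 0.006)
  # independence: empirical OR of an unlinked pair near 1
  tab <- table(m[, "e1"], m[, "e4"])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or, 0.75); expect_lt(or, 1.33)
  expect_error(
    ale_association(cat5, 0, lor_contemp = matrix(0, 2, 2)), "5 x 5")
})

test_that("missingness injection matches its rates and structure", {
  cat2 <- ale_catalog(c("A", "B"))
  pan <- ale_panel(tibble::tibble(
    id = rep(1:500, each = 10), hh_id = rep(1:500, each = 10),
    year = rep(2001:2010, 500), age = 30, A = 0L, B = 1L),
    catalog = cat2)
  expect_identical(inject_missingness(pan, 0, 0, seed = 1), pan)
  out <- inject_missingness(pan, cell_rate = 0.01, seed = 1)
  n_masked <- sum(is.na(as.matrix(out[c("A", "B")])))
  expect_gt(n_masked, 60)  # 95% binomial interval around 100 of 10,000
  expect_lt(n_masked, 140)
  rows <- inject_missingness(pan, full_row_rate = 0.05, seed = 2)
  mr <- is.na(as.matrix(rows[c("A", "B")]))
  expect_true(all(rowSums(mr) %in% c(0, 2))) # whole rows only
})
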