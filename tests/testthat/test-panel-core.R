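cat_ab <- ale_catalog(c("A", "B"))

test_that("CSV panels parse with NA tokens and empty cells as missing", {
  path <- write_panel_csv(c("id,hh_id,year,age,A,B",
                            "1,1,2001,30,1,NA",
                            "1,1,2002,31,0,0",
                            "2,2,2001,45,,1"))
  pan <- read_panel(path, cat_ab)
  expect_s3_class(pan, "ale_panel")
  expect_equal(nrow(pan), 3)
  expect_true(is.na(pan$B[1]))
  expect_true(is.na(pan$A[3]))
})

test_that("invalid input panels are hard errors, not silent fixes", {
  dup <- write_panel_csv(c("id,hh_id,year,age,A,B",
                           "1,1,2005,30,1,0",
                           "1,1,2005,30,0,0"))
  expect_error(read_panel(dup, cat_ab), "duplicate")
  unk <- write_panel_csv(c("id,hh_id,year,age,A,B,C",
                           "1,1,2001,30,1,0,0"))
  expect_error(read_panel(unk, cat_ab), "unknown event")
  catx <- ale_catalog(c("A", "B"), exclusivity_groups = list(c("A", "B")))
  bad <- write_panel_csv(c("id,hh_id,year,age,A,B",
                           "1,1,2001,30,1,1"))
  expect_error(read_panel(bad, catx), "exclusivity")
  rng <- write_panel_csv(c("id,hh_id,year,age,A,B",
                           "1,1,2001,30,2,0"))
  expect_error(read_panel(rng, cat_ab), "outside")
})

test_that("adult filter keeps the age-18 boundary inclusive", {
  pan <- ale_panel(tibble::tibble(
    id = 1:3, hh_id = 1:3, year = 2001, age = c(17, 18, 40),
    A = 0L, B = 0L), catalog = cat_ab)
  expect_message(out <- filter_adults(pan), "1 person-years")
  expect_equal(sort(out$age), c(18, 40))
  expect_message(same <- filter_adults(out), "0 person-years")
  expect_equal(nrow(same), 2)
})

test_that("fully missing person-years are dropped and masked cells imputed", {
  pan <- ale_panel(tibble::tibble(
    id = 1:5, hh_id = 1:5, year = 2001, age = 30,
    A = c(1L, NA, 0L, NA, 1L), B = c(NA, NA, 0L, 1L, 0L)),
    catalog = cat_ab)
  expect_message(out <- drop_all_missing_rows(pan), "1 fully missing")
  expect_equal(nrow(out), 4)
  imp <- impute_missing_as_zero(out)
  expect_equal(imp$A, c(1L, 0L, 0L, 1L))
  expect_equal(sum(attr(imp, "miss_mask")), 2)
  # imputation never increases counts
  expect_true(all(yearly_counts(imp) <= yearly_counts(out, na.rm = TRUE) +
                    rowSums(is.na(as.matrix(out[c("A", "B")])))))
  expect_true(sum(yearly_counts(imp)) == sum(yearly_counts(out, na.rm = TRUE)))
})

test_that("filtering order does not matter (adults vs missing-drop)", {
  set.seed(8)
  n <- 60
  pan <- ale_panel(tibble::tibble(
    id = 1:n, hh_id = 1:n, year = 2001,
    age = sample(10:60, n, TRUE),
    A = sample(c(0L, 1L, NA), n, TRUE),
    B = sample(c(0L, 1L, NA), n, TRUE)), catalog = cat_ab)
  a <- suppressMessages(drop_all_missing_rows(filter_adults(pan)))
  b <- suppressMessages(filter_adults(drop_all_missing_rows(pan)))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("consecutive windows keep the earliest gap-free run only", {
  mk <- function(id, years) tibble::tibble(
    id = id, hh_id = id, year = years, age = 30, A = 0L, B = 0L)
  pan <- ale_panel(rbind(mk(1, 2001:2020),
                         mk(2, c(2001:2010, 2012:2022)),
                         mk(3, c(1999:2003, 2010:2030))),
                   catalog = cat_ab)
  out <- consecutive_window(pan, 20)
  expect_equal(sort(unique(out$id)), c(1, 3)) # 2 has a gap before year 20
  expect_equal(out$year[out$id == 1], 2001:2020)
  expect_equal(out$year[out$id == 3], 2010:2029) # earliest 20-year run
  out10 <- consecutive_window(pan, 10)
  # individual 2 has runs of 10 and 11; the earliest (2001-2010) is kept
  expect_equal(out10$year[out10$id == 2], 2001:2010)
  # row-count contract: length x retained individuals
  expect_equal(nrow(out10), 10 * length(unique(out10$id)))
})

test_that("window retention matches a brute-force run scan", {
  set.seed(11)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    yrs <- sort(sample(2001:2020, sample(3:18, 1)))
    tibble::tibble(id = i, hh_id = i, year = yrs, age = 30, A = 0L, B = 0L)
  }))
  pan <- ale_panel(rows, catalog = cat_ab)
  len <- 6
  keep_brute <- vapply(1:40, function(i) {
    yrs <- sort(rows$year[rows$id == i])
    any(vapply(yrs, function(y0) all((y0:(y0 + len - 1)) %in% yrs),
               logical(1)))
  }, logical(1))
  out <- consecutive_window(pan, len)
  expect_equal(sort(unique(out$id)), which(keep_brute))
})

test_that("lag alignment pairs adjacent observed years only", {
  pan <- ale_panel(tibble::tibble(
    id = c(1, 1, 1, 2), hh_id = c(1, 1, 9, 2),
    year = c(2001, 2002, 2004, 2005), age = c(30, 31, 33, 50),
    A = c(1L, 0L, 1L, 0L), B = c(0L, 1L, 0L, 0L)), catalog = cat_ab)
  al <- lag_align(pan)
  expect_equal(nrow(al), 1) # only 2001 -> 2002; individual 2 has one year
  expect_equal(al$year, 2002)
  expect_equal(al$A_lag, 1L)
  expect_equal(al$B_out, 1L)
  # the pair count equals the adjacent-year count per individual
  set.seed(4)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    yrs <- sort(sample(2001:2012, sample(2:10, 1)))
    tibble::tibble(id = i, hh_id = i, year = yrs, age = 30,
                   A = sample(0:1, length(yrs), TRUE), B = 0L)
  }))
  pan2 <- ale_panel(rows, catalog = cat_ab)
  n_pairs <- sum(vapply(1:30, function(i)
    sum(diff(sort(rows$year[rows$id == i])) == 1), numeric(1)))
  expect_equal(nrow(lag_align(pan2)), n_pairs)
  # outcome-year household id is attached
  al1 <- lag_align(pan)
  expect_equal(al1$hh_id, 1)
})

test_that("count summaries match hand and brute-force tallies", {
  pan <- ale_panel(tibble::tibble(
    id = c(1, 2), hh_id = c(1, 2), year = 2001, age = 30,
    A = c(1L, 1L), B = c(0L, 1L)), catalog = cat_ab)
  s <- count_summaries(pan)
  expect_equal(s$event_frequencies$rel_freq, c(2 / 3, 1 / 3))
  expect_equal(sort(yearly_counts(pan)), c(1, 2))
  expect_equal(sum(s$event_frequencies$rel_freq), 1)
  zero <- ale_panel(tibble::tibble(
    id = 1:3, hh_id = 1:3, year = 2001, age = 30, A = 0L, B = 0L),
    catalog = cat_ab)
  sz <- count_summaries(zero)
  expect_equal(sz$event_frequencies$rel_freq, c(0, 0))
  expect_true(all(sz$cumulative$total == 0))
  # random panel: frequencies equal a direct tally
  set.seed(2)
  pr <- ale_panel(tibble::tibble(
    id = rep(1:20, each = 3), hh_id = rep(1:20, each = 3),
    year = rep(2001:2003, 20), age = 30,
    A = sample(0:1, 60, TRUE), B = sample(0:1, 60, TRUE)),
    catalog = cat_ab)
  sr <- count_summaries(pr)
  expect_equal(sr$event_frequencies$n, c(sum(pr$A), sum(pr$B)))
  expect_equal(sr$cumulative$total,
               as.integer(tapply(pr$A + pr$B, pr$id, sum)[
                 as.character(sr$cumulative$id)]),
               ignore_attr = TRUE)
})

test_that("joint and conditional probabilities agree with brute force", {
  pan <- ale_panel(tibble::tibble(
    id = 1:4, hh_id = 1:4, year = 2001, age = 30,
    A = c(1L, 1L, 0L, 0L), B = c(1L, 0L, 1L, 0L)), catalog = cat_ab)
  jp <- joint_conditional_probs(pan)
  expect_equal(jp$joint["A", "B"], 0.25)
  expect_equal(jp$joint, t(jp$joint)) # symmetry
  # P(A|B) P(B) = P(B|A) P(A)
  expect_equal(jp$conditional["B", "A"] * jp$joint["B", "B"],
               jp$conditional["A", "B"] * jp$joint["A", "A"])
  set.seed(5)
  cat3 <- ale_catalog(c("A", "B", "C"))
  m <- matrix(sample(c(0L, 1L, NA), 300, TRUE, prob = c(.6, .3, .1)),
              ncol = 3, dimnames = list(NULL, cat3$events))
  panr <- ale_panel(cbind(tibble::tibble(id = 1:100, hh_id = 1:100,
                                         year = 2001, age = 30),
                          as.data.frame(m)),
                    catalog = cat3, validate = FALSE)
  jpr <- joint_conditional_probs(panr)
  ref <- brute_joint_cond(m)
  expect_equal(jpr$joint, ref$joint)
  expect_equal(jpr$conditional, ref$conditional)
  # a mutually exclusive pair has joint probability zero by construction
  catx <- ale_catalog(c("A", "B"), exclusivity_groups = list(c("A", "B")))
  panx <- ale_panel(tibble::tibble(
    id = 1:4, hh_id = 1:4, year = 2001, age = 30,
    A = c(1L, 0L, 0L, 0L), B = c(0L, 1L, 1L, 0L)), catalog = catx)
  expect_equal(joint_conditional_probs(panx)$joint["A", "B"], 0)
})

test_that("cross-wave household ids follow exact membership equality", {
  mem <- data.frame(
    wave = c(1, 1, 2, 2, 3, 3),
    household = c("h1", "h1", "h1", "h1", "h1", "h1"),
    individual = c("A", "B", "A", "B", "A", "B"))
  ids <- build_household_ids(mem)
  expect_equal(length(unique(ids$cross_hh_id)), 1)
  # a member joining creates a new id
  mem2 <- rbind(mem[1:4, ],
                data.frame(wave = 3, household = "h1",
                           individual = c("A", "B", "C")))
  ids2 <- build_household_ids(mem2)
  expect_equal(length(unique(ids2$cross_hh_id)), 2)
  # merging two singles creates a third id
  mem3 <- data.frame(
    wave = c(1, 1, 2, 2),
    household = c("h1", "h2", "h3", "h3"),
    individual = c("A", "B", "A", "B"))
  ids3 <- build_household_ids(mem3)
  expect_equal(length(unique(ids3$cross_hh_id)), 3)
  dup <- data.frame(wave = c(1, 1), household = c("h1", "h2"),
                    individual = c("A", "A"))
  expect_error(build_household_ids(dup), "two households")
})
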