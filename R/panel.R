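#' Person-year panel datasets
#'
#' An `ale_panel` is a tibble of person-year rows with columns `id`, `hh_id`,
#' `year`, `age` and either one 0/1/NA column per catalog event (an *event
#' panel*) or a single non-negative `count` column (a *count panel*, as
#' produced by the count-level generators). The attached catalog defines the
#' event order, exclusivity groups, and the beta-binomial trial count.
#' Missing event indicators are stored as `NA`; after
#' [impute_missing_as_zero()] they are set to 0 and the audit mask is kept as
#' the `miss_mask` attribute.
#'
#' @param data a data frame with the columns above.
#' @param catalog an [ale_catalog()]; `NULL` for count panels.
#' @param provenance free-text description of where the rows came from.
#' @param validate check invariants (unique `(id, year)`, single household
#'   per person-year, exclusivity).
#' @return an `ale_panel` tibble.
#' @export
ale_panel <- function(data, catalog = NULL, provenance = "unspecified",
                      validate = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("id", "hh_id", "year")
  if (!all(need %in% names(data)))
    stop_ale("panel must have columns %s", paste(need, collapse = ", "))
  is_count <- "count" %in% names(data) && is.null(catalog)
  if (!is_count) {
    if (is.null(catalog)) stop_ale("event panels need a catalog")
    missing_cols <- setdiff(catalog$events, names(data))
    if (length(missing_cols))
      stop_ale("panel lacks event column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  out <- structure(data,
                   class = c("ale_panel", class(tibble::tibble())),
                   catalog = catalog, provenance = provenance)
  if (validate) validate_panel(out)
  out
}

panel_catalog <- function(panel) attr(panel, "catalog")

#' @rdname ale_panel
#' @param panel an `ale_panel`.
#' @export
is_count_panel <- function(panel) {
  "count" %in% names(panel) && is.null(panel_catalog(panel))
}

validate_panel <- function(panel) {
  key <- paste(panel$id, panel$year)
  if (anyDuplicated(key))
    stop_ale("duplicate (id, year) pairs: %s",
             paste(head(unique(key[duplicated(key)]), 5), collapse = "; "),
             class = "alepanel_duplicate_key")
  hh_key <- !duplicated(key) # one hh per (id, year) is implied by uniqueness
  cat <- panel_catalog(panel)
  if (!is.null(cat) && length(cat$exclusivity_groups)) {
    for (g in cat$exclusivity_groups) {
      s <- rowSums(as.matrix(panel[g]) == 1, na.rm = TRUE)
      if (any(s > 1))
        stop_ale("exclusivity violated in rows: %s",
                 paste(head(which(s > 1), 10), collapse = ", "),
                 class = "alepanel_exclusivity")
    }
  }
  invisible(panel)
}

restore_panel <- function(data, template, provenance = NULL) {
  ale_panel(data, catalog = panel_catalog(template),
            provenance = provenance %||% attr(template, "provenance"),
            validate = FALSE)
}

#' @method print ale_panel
#' @export
print.ale_panel <- function(x, ...) {
  cat("<ale_panel> ", nrow(x), " person-years, ",
      length(unique(x$id)), " individuals, ",
      length(unique(x$hh_id)), " households",
      if (is_count_panel(x)) " (counts)" else "", "\n", sep = "")
  NextMethod()
}

events_matrix <- function(panel) {
  cat <- panel_catalog(panel)
  if (is.null(cat)) stop_ale("not an event panel")
  m <- as.matrix(panel[cat$events])
  storage.mode(m) <- "integer"
  m
}

#' Yearly event counts of a panel
#'
#' For an event panel, the per-row count of events (`NA` treated as not
#' observed: rows with any `NA` give `NA` unless `na.rm = TRUE`); for a count
#' panel, the `count` column.
#'
#' @param panel an `ale_panel`.
#' @param na.rm sum over observed indicators only.
#' @return integer vector of yearly counts.
#' @export
yearly_counts <- function(panel, na.rm = TRUE) {
  if (is_count_panel(panel)) return(as.integer(panel$count))
  as.integer(rowSums(events_matrix(panel), na.rm = na.rm))
}

#' Restrict a panel to adults
#'
#' Keeps person-years with `age >= 18` (inclusive boundary); the number of
#' removed rows is reported via a message.
#'
#' @param panel an `ale_panel` with `age` present for every row.
#' @return the filtered panel.
#' @export
filter_adults <- function(panel) {
  if (!"age" %in% names(panel) || anyNA(panel$age))
    stop_ale("age must be present for all rows")
  keep <- panel$age >= 18
  message(sum(!keep), " person-years below age 18 removed")
  restore_panel(panel[keep, , drop = FALSE], panel)
}

#' Drop person-years with all events missing
#'
#' @param panel an event `ale_panel`.
#' @return the filtered panel; removed-row count reported via message.
#' @export
drop_all_missing_rows <- function(panel) {
  m <- events_matrix(panel)
  all_miss <- rowSums(!is.na(m)) == 0L
  message(sum(all_miss), " fully missing person-years removed")
  restore_panel(panel[!all_miss, , drop = FALSE], panel)
}

#' Count missing events as not having occurred
#'
#' Sets `NA` event cells to 0. The pattern of imputed cells is retained in
#' the `miss_mask` attribute (a logical matrix aligned to the catalog) so the
#' imputation rate stays reportable.
#'
#' @param panel an event `ale_panel`.
#' @return the imputed panel.
#' @export
impute_missing_as_zero <- function(panel) {
  cat <- panel_catalog(panel)
  m <- events_matrix(panel)
  mask <- is.na(m)
  m[mask] <- 0L
  out <- panel
  out[cat$events] <- as.data.frame(m)
  out <- restore_panel(out, panel)
  attr(out, "miss_mask") <- mask
  out
}

#' Earliest run of consecutive observation years per individual
#'
#' Keeps, for each individual, the earliest run of exactly `length` calendar
#' years observed without gaps (`year[t+1] == year[t] + 1`); individuals with
#' no such run are dropped. The output therefore has
#' `length * n_retained_individuals` rows.
#'
#' @param panel an `ale_panel`.
#' @param length window length in years (>= 2).
#' @return the windowed panel.
#' @export
consecutive_window <- function(panel, length) {
  stopifnot(length >= 2)
  ord <- order(panel$id, panel$year)
  p <- panel[ord, , drop = FALSE]
  keep <- logical(nrow(p))
  idx <- split(seq_len(nrow(p)), p$id)
  for (rows in idx) {
    yrs <- p$year[rows]
    # run ids: increments where the gap to the previous year is not 1
    run <- cumsum(c(TRUE, diff(yrs) != 1L))
    for (r in unique(run)) {
      in_run <- which(run == r)
      if (base::length(in_run) >= length) {
        keep[rows[in_run[seq_len(length)]]] <- TRUE
        break # earliest qualifying run only
      }
    }
  }
  restore_panel(p[keep, , drop = FALSE], panel)
}

#' Align predictor and outcome years one year apart
#'
#' Emits one row per (individual, year t, year t+1) pair where both years are
#' observed. Predictor-year columns get suffix `_lag`; outcome-year event (or
#' count) columns get suffix `_out`. The household id and age attached are
#' those of the outcome year (household membership can change between
#' years).
#'
#' @param panel an `ale_panel`.
#' @return a tibble of aligned pairs with columns `id`, `hh_id`, `year`
#'   (outcome year), `age` (outcome year, if present), `*_lag`, `*_out`.
#' @export
lag_align <- function(panel) {
  ord <- order(panel$id, panel$year)
  p <- panel[ord, , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(tibble::tibble())
  pred <- seq_len(n - 1)
  ok <- p$id[pred] == p$id[pred + 1] & p$year[pred + 1] == p$year[pred] + 1L
  pred <- pred[ok]
  outc <- pred + 1L
  val_cols <- if (is_count_panel(p)) "count" else panel_catalog(p)$events
  out <- tibble::tibble(
    id = p$id[outc], hh_id = p$hh_id[outc], year = p$year[outc])
  if ("age" %in% names(p)) out$age <- p$age[outc]
  for (v in val_cols) {
    out[[paste0(v, "_lag")]] <- p[[v]][pred]
    out[[paste0(v, "_out")]] <- p[[v]][outc]
  }
  attr(out, "catalog") <- panel_catalog(p)
  out
}

#' Descriptive count summaries
#'
#' @param panel an `ale_panel` (event panels are summed over observed
#'   indicators).
#' @return a list with elements
#'   `count_distribution` (tibble: `count`, `n`, `prop` over person-years),
#'   `event_frequencies` (event panels only; tibble: `event`, `n`,
#'   `rel_freq`, relative frequencies summing to 1 over events),
#'   `cumulative` (tibble: `id`, `total` over the individual's observed
#'   years), and `cumulative_stats` (mean, median, min, max, plus both
#'   dispersion statistics `sd_over_mean` and `var_over_mean`, named
#'   unambiguously).
#' @export
count_summaries <- function(panel) {
  yc <- yearly_counts(panel)
  cd <- as.data.frame(table(count = yc), stringsAsFactors = FALSE)
  cd$count <- as.integer(cd$count)
  count_distribution <- tibble::tibble(
    count = cd$count, n = cd$Freq, prop = cd$Freq / sum(cd$Freq))
  event_frequencies <- NULL
  if (!is_count_panel(panel)) {
    m <- events_matrix(panel)
    tot <- colSums(m, na.rm = TRUE)
    event_frequencies <- tibble::tibble(
      event = colnames(m), n = as.integer(tot),
      rel_freq = if (sum(tot) > 0) unname(tot / sum(tot)) else rep(0, length(tot)))
  }
  cum <- rowsum(yc, panel$id)
  cumulative <- tibble::tibble(id = rownames(cum), total = as.integer(cum[, 1]))
  tot <- cumulative$total
  cumulative_stats <- tibble::tibble(
    mean = mean(tot), median = median(tot),
    min = min(tot), max = max(tot),
    sd_over_mean = if (mean(tot) > 0) sd(tot) / mean(tot) else NA_real_,
    var_over_mean = if (mean(tot) > 0) var(tot) / mean(tot) else NA_real_)
  list(count_distribution = count_distribution,
       event_frequencies = event_frequencies,
       cumulative = cumulative,
       cumulative_stats = cumulative_stats)
}

#' Within-year joint and conditional event probabilities
#'
#' Empirical probabilities over person-years: `joint[A, B] = P(A = 1, B = 1)`
#' and `conditional[B, A] = P(A = 1 | B = 1)` (row = conditioning/predictor
#' event, column = outcome event). Cells conditioning on an event that never
#' occurs are `NA` (undefined). Rows with missing values in a pair are
#' dropped pairwise.
#'
#' @param panel an event `ale_panel`.
#' @return list with matrices `joint` and `conditional`.
#' @export
joint_conditional_probs <- function(panel) {
  m <- events_matrix(panel)
  p <- ncol(m)
  joint <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  cond <- joint
  for (a in seq_len(p)) for (b in seq_len(p)) {
    ok <- !is.na(m[, a]) & !is.na(m[, b])
    if (!any(ok)) next
    joint[a, b] <- mean(m[ok, a] == 1 & m[ok, b] == 1)
    pb <- mean(m[ok, a] == 1) # row a is the conditioning event
    cond[a, b] <- if (pb > 0) mean(m[ok, a] == 1 & m[ok, b] == 1) / pb else NA_real_
  }
  list(joint = joint, conditional = cond)
}
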