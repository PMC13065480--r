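#' Read a long-format person-year panel from CSV
#'
#' Expects header columns `id`, `hh_id`, `year`, `age`, then one column per
#' catalog event with values in 0/1/NA (the literal token `NA` or an empty
#' cell both count as missing). Rows violating the panel invariants are hard
#' errors, not silent fixes: duplicate `(id, year)` keys, event columns not
#' in the catalog, and within-group exclusivity violations all abort with
#' the offending rows named.
#'
#' @param path CSV file path.
#' @param catalog an [ale_catalog()].
#' @return a validated [ale_panel()].
#' @export
read_panel <- function(path, catalog) {
  df <- read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  need <- c("id", "hh_id", "year", "age")
  if (!all(need %in% names(df)))
    stop_ale("missing required column(s): %s",
             paste(setdiff(need, names(df)), collapse = ", "))
  extra <- setdiff(names(df), c(need, catalog$events))
  if (length(extra))
    stop_ale("unknown event column(s): %s", paste(extra, collapse = ", "))
  for (e in catalog$events) {
    v <- df[[e]]
    if (!all(v %in% c(0L, 1L) | is.na(v)))
      stop_ale("event column %s has values outside {0, 1, NA}", e)
    df[[e]] <- as.integer(v)
  }
  ale_panel(df, catalog = catalog, provenance = paste0("file:", path))
}

#' Write a panel (or any tidy table) to CSV
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Cross-wave household identifiers from per-wave membership
#'
#' Two wave-households receive the same cross-wave id iff their member sets
#' are exactly equal; any change in composition (an individual entering or
#' leaving, households merging or splitting) creates a new id.
#'
#' @param membership a data frame with columns `wave`, `household` (the
#'   per-wave household label), and `individual`.
#' @return a tibble `wave`, `household`, `cross_hh_id`.
#' @export
build_household_ids <- function(membership) {
  m <- as.data.frame(membership)
  stopifnot(all(c("wave", "household", "individual") %in% names(m)))
  key_wh <- paste(m$wave, m$individual)
  dup <- duplicated(key_wh)
  if (any(dup))
    stop_ale("individual(s) in two households within one wave: %s",
             paste(head(unique(m$individual[dup]), 5), collapse = ", "))
  wh <- unique(m[c("wave", "household")])
  member_key <- vapply(seq_len(nrow(wh)), function(i) {
    ids <- m$individual[m$wave == wh$wave[i] & m$household == wh$household[i]]
    paste(sort(as.character(ids)), collapse = "\r")
  }, character(1))
  tibble::tibble(wave = wh$wave, household = wh$household,
                 cross_hh_id = as.integer(factor(member_key,
                                                 levels = unique(member_key))))
}
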