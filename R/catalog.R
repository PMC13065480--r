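#' Event catalog
#'
#' An event catalog names the adverse life events recorded by a panel study,
#' declares which events are mutually exclusive subcategories of one another
#' (at most one member can be recorded per person-year), and fixes the number
#' of independent event "slots" per person-year, `k_trials`, used as the trial
#' count of the beta-binomial accumulation model. A group of g mutually
#' exclusive events contributes a single slot, so
#' `k_trials = n_events - sum(group sizes - 1)`.
#'
#' @param events character vector of event labels (order is meaningful: it is
#'   the sampling order of the dependence generator and the column order of
#'   all matrices).
#' @param exclusivity_groups list of character vectors; each vector is a set
#'   of labels that cannot co-occur within a person-year. Groups must be
#'   disjoint subsets of `events`.
#' @param reference optional label used as the dropped reference category in
#'   co-occurrence models; must belong to exactly one exclusivity group.
#' @return an object of class `ale_catalog`.
#' @examples
#' cat6 <- ale_catalog(letters[1:6])
#' cat6$k_trials # 6
#' @export
ale_catalog <- function(events, exclusivity_groups = list(), reference = NULL) {
  events <- as.character(events)
  if (anyDuplicated(events)) stop_ale("duplicate event labels in catalog")
  if (length(exclusivity_groups)) {
    all_members <- unlist(exclusivity_groups)
    if (!all(all_members %in% events))
      stop_ale("exclusivity group member(s) not in event list: %s",
               paste(setdiff(all_members, events), collapse = ", "))
    if (anyDuplicated(all_members))
      stop_ale("exclusivity groups must be disjoint")
  }
  if (!is.null(reference)) {
    in_grp <- vapply(exclusivity_groups, function(g) reference %in% g, logical(1))
    if (sum(in_grp) != 1L)
      stop_ale("reference label must belong to exactly one exclusivity group")
  }
  k <- length(events) -
    sum(vapply(exclusivity_groups, length, integer(1)) - 1L)
  structure(
    list(events = events,
         exclusivity_groups = lapply(exclusivity_groups, as.character),
         reference = reference,
         k_trials = as.integer(k)),
    class = "ale_catalog")
}

#' @method print ale_catalog
#' @export
print.ale_catalog <- function(x, ...) {
  cat("<ale_catalog> ", length(x$events), " events, k_trials = ", x$k_trials,
      "\n", sep = "")
  cat("  events:", paste(x$events, collapse = ", "), "\n")
  if (length(x$exclusivity_groups))
    for (g in x$exclusivity_groups)
      cat("  exclusive:", paste(g, collapse = " | "), "\n")
  if (!is.null(x$reference)) cat("  reference:", x$reference, "\n")
  invisible(x)
}

# events (if any) grouped into sampling "slots": each exclusivity group is a
# single slot placed at its first member's position; singletons are their own
# slot. Used by the dependence generator and by k_trials bookkeeping.
catalog_slots <- function(catalog) {
  ev <- catalog$events
  grp_of <- setNames(rep(NA_integer_, length(ev)), ev)
  for (gi in seq_along(catalog$exclusivity_groups))
    grp_of[catalog$exclusivity_groups[[gi]]] <- gi
  slots <- list()
  seen_grp <- integer(0)
  for (e in ev) {
    g <- grp_of[[e]]
    if (is.na(g)) {
      slots[[length(slots) + 1L]] <- e
    } else if (!(g %in% seen_grp)) {
      slots[[length(slots) + 1L]] <- catalog$exclusivity_groups[[g]]
      seen_grp <- c(seen_grp, g)
    }
  }
  slots
}

#' Catalogs emulating the two national panel instruments
#'
#' `catalog_swiss()` mirrors a 12-event instrument in which seven personal
#' illness/accident subcategories are mutually exclusive (only one such event
#' is recorded per year), giving `k_trials = 6`; the unspecified
#' illness/accident subcategory is the reference. `catalog_australia()`
#' mirrors a 13-event instrument with no exclusivity, `k_trials = 13`.
#' Event labels are synthetic descriptive stand-ins for the survey items.
#'
#' @return an [ale_catalog()].
#' @export
catalog_swiss <- function() {
  illness <- c("physical_illness", "mental_illness", "work_accident",
               "road_accident", "home_accident", "sport_accident",
               "other_illness_accident")
  ale_catalog(
    events = c(illness, "illness_close_person", "death_close_person",
               "conflicts_relatives", "problems_children", "end_relationship"),
    exclusivity_groups = list(illness),
    reference = "other_illness_accident")
}

#' @rdname catalog_swiss
#' @export
catalog_australia <- function() {
  ale_catalog(c(
    "serious_injury_illness", "injury_illness_family", "death_spouse_child",
    "death_relative", "death_friend", "victim_violence",
    "victim_property_crime", "detained_jail", "family_member_jailed",
    "fired", "finances_worsened", "separated", "natural_disaster"))
}
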