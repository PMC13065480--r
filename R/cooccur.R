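#' Odds-ratio matrices for event co-occurrence
#'
#' One binomial-logit mixed model per outcome event with crossed individual
#' and household random intercepts. In the adjusted analysis all other
#' events enter jointly as predictors; in the unadjusted sensitivity
#' analysis one predictor enters at a time, fitted to the same rows with
#' the same random-effects structure. Exclusivity handling: the catalog's
#' reference label is dropped as a predictor in every model, and when the
#' outcome belongs to an exclusivity group the other group members are
#' removed as contemporaneous predictors (they are structurally zero given
#' the outcome and would be perfectly collinear); those cells are reported
#' absent, never as OR = 0. In the lag-1 analysis the outcome is next
#' year's event, the outcome event type itself is included as a predictor
#' (the diagonal measures within-event persistence), and the household id
#' attached is that of the outcome year.
#'
#' @param panel an event `ale_panel`.
#' @param catalog the panel's [ale_catalog()].
#' @param adjusted all-predictor models (`TRUE`) or one-predictor-at-a-time
#'   sensitivity models (`FALSE`).
#' @param ci `"wald"` (default; per-matrix runs) or `"profile"`
#'   (per-cell profile likelihood; considerably more expensive).
#' @param level confidence level.
#' @param control a [glmm_control()].
#' @return an `ale_ormatrix`: a tibble with one row per (outcome,
#'   predictor) cell — `outcome`, `predictor`, `lagged`, `adjusted`, `or`,
#'   `conf_low`, `conf_high`, `significant`, `n_obs`, `status` — plus
#'   per-model metadata in `attr(, "models")`.
#' @export
fit_contemporaneous <- function(panel, catalog, adjusted = TRUE,
                                ci = c("wald", "profile"), level = 0.95,
                                control = glmm_control()) {
  cooccur_engine(panel, catalog, lagged = FALSE, adjusted = adjusted,
                 ci = match.arg(ci), level = level, control = control)
}

#' @rdname fit_contemporaneous
#' @export
fit_lag1 <- function(panel, catalog, adjusted = TRUE,
                     ci = c("wald", "profile"), level = 0.95,
                     control = glmm_control()) {
  cooccur_engine(panel, catalog, lagged = TRUE, adjusted = adjusted,
                 ci = match.arg(ci), level = level, control = control)
}

#' @rdname fit_contemporaneous
#' @param lagged fit the lag-1 variant.
#' @export
fit_unadjusted <- function(panel, catalog, lagged = FALSE,
                           ci = c("wald", "profile"), level = 0.95,
                           control = glmm_control()) {
  cooccur_engine(panel, catalog, lagged = lagged, adjusted = FALSE,
                 ci = match.arg(ci), level = level, control = control)
}

group_of <- function(catalog, event) {
  for (g in catalog$exclusivity_groups) if (event %in% g) return(g)
  NULL
}

cooccur_engine <- function(panel, catalog, lagged, adjusted, ci, level,
                           control) {
  events <- catalog$events
  if (length(events) < 2) stop_ale("need at least two events")
  if (lagged) {
    al <- lag_align(panel)
    if (!nrow(al)) stop_ale("no adjacent year pairs for the lag-1 analysis")
    frame <- data.frame(individual = al$id, household = al$hh_id)
    for (e in events) {
      frame[[paste0("p_", e)]] <- al[[paste0(e, "_lag")]]
      frame[[paste0("o_", e)]] <- al[[paste0(e, "_out")]]
    }
  } else {
    frame <- data.frame(individual = panel$id, household = panel$hh_id)
    for (e in events) {
      frame[[paste0("p_", e)]] <- panel[[e]]
      frame[[paste0("o_", e)]] <- panel[[e]]
    }
  }
  frame <- frame[complete.cases(frame), , drop = FALSE]
  z <- qnorm(1 - (1 - level) / 2)
  cells <- list()
  models <- list()
  for (outc in events) {
    grp <- group_of(catalog, outc)
    preds <- setdiff(events, outc)
    if (!is.null(catalog$reference)) preds <- setdiff(preds, catalog$reference)
    dropped <- character(0)
    if (!lagged && !is.null(grp)) {
      dropped <- intersect(preds, grp)
      preds <- setdiff(preds, grp)
    }
    # lag-1 models include the outcome's own type as predictor
    preds_full <- if (lagged) union(outc, preds) else preds
    preds_full <- intersect(events, preds_full) # catalog order
    if (lagged && !is.null(catalog$reference))
      preds_full <- setdiff(preds_full, catalog$reference)
    pred_sets <- if (adjusted) list(preds_full) else as.list(preds_full)
    for (ps in pred_sets) {
      pcols <- paste0("p_", ps)
      df <- frame[c(paste0("o_", outc), pcols, "individual", "household")]
      names(df)[1] <- "y"
      names(df)[seq_along(pcols) + 1] <- ps
      df <- aggregate_weighted(df) # binary rows collapse within entities
      spec <- glmm_spec("binomial", response = "y", fixed = ps,
                        groups = c("individual", "household"), trials = 1)
      fit <- tryCatch(
        withCallingHandlers(
          fit_glmm(spec, df, weights = df$weight, control = control),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      key <- paste(outc, paste(ps, collapse = "+"))
      if (inherits(fit, "error")) {
        for (x in ps)
          cells[[paste(outc, x)]] <- or_cell(outc, x, lagged, adjusted,
                                             status = paste0("fit_error:",
                                                             conditionMessage(fit)))
        next
      }
      models[[key]] <- list(outcome = outc, predictors = ps,
                            n_obs = fit$n_obs, n_groups = fit$n_groups,
                            convergence = fit$convergence, flags = fit$flags)
      for (x in ps) {
        sep <- paste0("separation:", x) %in% fit$flags
        if (sep) {
          cells[[paste(outc, x)]] <- or_cell(outc, x, lagged, adjusted,
                                             n_obs = fit$n_obs,
                                             status = "absent_separation")
          next
        }
        b <- fit$coefficients[[x]]
        if (ci == "profile") {
          bounds <- tryCatch(profile_ci(fit, x, level),
                             error = function(e) c(NA_real_, NA_real_))
          lohi <- exp(bounds)
        } else {
          se <- fit$se_fixed[[x]]
          lohi <- exp(c(b - z * se, b + z * se))
        }
        cells[[paste(outc, x)]] <- or_cell(
          outc, x, lagged, adjusted, or = exp(b),
          lo = lohi[1], hi = lohi[2], n_obs = fit$n_obs, status = "ok")
      }
    }
    for (x in dropped)
      cells[[paste(outc, x)]] <- or_cell(outc, x, lagged, adjusted,
                                         status = "absent_exclusivity")
  }
  out <- do.call(rbind, unname(cells))
  out <- out[order(match(out$outcome, events), match(out$predictor, events)), ]
  structure(out, class = c("ale_ormatrix", class(out)),
            models = models, level = level, lagged = lagged,
            adjusted = adjusted)
}

or_cell <- function(outcome, predictor, lagged, adjusted, or = NA_real_,
                    lo = NA_real_, hi = NA_real_, n_obs = NA_real_,
                    status = "ok") {
  tibble::tibble(outcome = outcome, predictor = predictor, lagged = lagged,
                 adjusted = adjusted, or = or, conf_low = lo,
                 conf_high = hi,
                 significant = !is.na(lo) & !is.na(hi) & (lo > 1 | hi < 1),
                 n_obs = n_obs, status = status)
}

#' Heat-map-ready wide odds-ratio matrix
#'
#' @param x an `ale_ormatrix`.
#' @param value which column to spread.
#' @return a matrix with rows = predictors and columns = outcomes; absent
#'   cells are `NA`.
#' @export
or_matrix_wide <- function(x, value = "or") {
  preds <- unique(x$predictor); outs <- unique(x$outcome)
  m <- matrix(NA_real_, length(preds), length(outs),
              dimnames = list(predictor = preds, outcome = outs))
  ok <- x$status == "ok"
  m[cbind(match(x$predictor[ok], preds), match(x$outcome[ok], outs))] <-
    x[[value]][ok]
  m
}

#' Percentage difference between unadjusted and adjusted odds ratios
#'
#' `100 * (or_unadjusted - or_adjusted) / or_adjusted`.
#'
#' @param or_unadjusted,or_adjusted odds ratios (vectorized);
#'   `or_adjusted` must be positive.
#' @return percentage difference(s).
#' @export
percent_difference <- function(or_unadjusted, or_adjusted) {
  if (any(or_adjusted <= 0, na.rm = TRUE))
    stop_ale("adjusted odds ratios must be positive")
  100 * (or_unadjusted - or_adjusted) / or_adjusted
}

#' Join adjusted and unadjusted matrices cell by cell
#'
#' @param adjusted,unadjusted aligned `ale_ormatrix` objects (same outcome
#'   and predictor cells, same lag setting).
#' @return a tibble with both ORs, the percentage difference, and a
#'   direction-reversal flag for cells significant in the adjusted fit.
#' @export
compare_adjustment <- function(adjusted, unadjusted) {
  a <- adjusted[adjusted$status == "ok",
                c("outcome", "predictor", "or", "conf_low", "conf_high",
                  "significant")]
  u <- unadjusted[unadjusted$status == "ok",
                  c("outcome", "predictor", "or")]
  names(a)[3:6] <- c("or_adjusted", "adj_low", "adj_high", "adj_significant")
  names(u)[3] <- "or_unadjusted"
  m <- merge(as.data.frame(a), as.data.frame(u),
             by = c("outcome", "predictor"))
  m$pct_difference <- percent_difference(m$or_unadjusted, m$or_adjusted)
  m$reversal <- m$adj_significant &
    ((m$or_adjusted > 1 & m$or_unadjusted < 1) |
       (m$or_adjusted < 1 & m$or_unadjusted > 1))
  tibble::as_tibble(m)
}

#' Significant adjusted associations that reverse direction unadjusted
#'
#' Returns the cells whose adjusted OR is significant (CI excludes 1) and
#' whose unadjusted OR lies on the other side of 1.
#'
#' @inheritParams compare_adjustment
#' @return a tibble of reversed cells (possibly empty).
#' @export
sign_reversals <- function(adjusted, unadjusted) {
  cmp <- compare_adjustment(adjusted, unadjusted)
  cmp[cmp$reversal, , drop = FALSE]
}
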