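#' Run a configuration-driven synthetic study end to end
#'
#' Executes simulate -> filters -> enabled analyses, writing tidy outputs
#' and a JSON run manifest (package version, seed, configuration, stage
#' timings, output files with checksums). Identical configurations yield
#' byte-identical numerical outputs: all randomness flows from the single
#' mandatory seed through named sub-streams.
#'
#' The configuration is a named list (or a YAML file path) with fields:
#' \describe{
#'   \item{seed}{integer, mandatory.}
#'   \item{generator}{`model` (one of `poisson`, `frailty`, `urn`,
#'     `typed`), `n_individuals`, `n_years`, optional `n_households`, and
#'     the model's parameters (`rate`, `sd_individual`, `sd_household`;
#'     `white`, `blue`, `reinforcement`, `draws_per_year`;
#'     `base_logits`).}
#'   \item{catalog}{`"swiss"`, `"australia"`, or a list with `events` /
#'     `exclusivity_groups` / `reference` (typed generator only).}
#'   \item{analyses}{any of `summaries`, `cooccur`, `lag1`,
#'     `autocorrelation`, `accumulation` (with optional `window`),
#'     `tailfit` (with optional `distributions`).}
#'   \item{output_dir}{where results are written.}
#' }
#'
#' @param config a named list or a YAML file path.
#' @return the manifest (invisibly also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_ale("config validation: seed is mandatory")
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- config$generator
  if (is.null(gen$model)) stop_ale("config validation: generator.model missing")
  analyses <- config$analyses %||% list("summaries")
  if (!is.list(analyses))
    analyses <- setNames(rep(list(TRUE), length(analyses)), analyses)

  manifest <- list(package = "alepanel",
                   version = as.character(utils::packageVersion("alepanel")),
                   seed = seed, config = config, stages = list(),
                   outputs = character(0))
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      status = if (inherits(val, "error")) "failed" else "ok")
    if (inherits(val, "error")) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(val)
      write_manifest(manifest, out_dir)
      stop_ale("stage '%s' failed: %s", name, conditionMessage(val))
    }
    val
  }
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(x)) write_tidy_csv(x, path)
    else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    manifest$outputs <<- c(manifest$outputs, file)
    invisible(path)
  }

  catalog <- resolve_catalog(config$catalog)
  panel <- stage("simulate", {
    n <- gen$n_individuals %||% 500
    T_ <- gen$n_years %||% 20
    hh <- if (!is.null(gen$n_households))
      make_household_map(n, gen$n_households, seed) else NULL
    switch(gen$model,
      poisson = simulate_poisson_panel(gen$rate %||% 0.5, n, T_, seed),
      frailty = simulate_frailty_panel(
        frailty_params(gen$rate %||% 0.5, gen$sd_individual %||% 0.3,
                       gen$sd_household %||% 0.3),
        hh %||% make_household_map(n, max(1, round(n * 0.8)), seed), T_, seed),
      urn = simulate_urn_panel(
        urn_spec(gen$white %||% 6, gen$blue %||% 1,
                 gen$reinforcement %||% 1, gen$draws_per_year %||% 6),
        n, T_, seed, household_map = hh),
      typed = simulate_typed_panel(
        ale_association(catalog, gen$base_logits %||% -3,
                        sd_individual = gen$sd_individual %||% 0,
                        sd_household = gen$sd_household %||% 0),
        n, T_, seed, household_map = hh),
      stop_ale("unknown generator model '%s'", gen$model))
  })
  panel <- stage("filters", suppressMessages(filter_adults(panel)))

  if (!is.null(analyses$summaries)) stage("summaries", {
    s <- count_summaries(panel)
    emit(s$count_distribution, "count_distribution.csv")
    if (!is.null(s$event_frequencies))
      emit(s$event_frequencies, "event_frequencies.csv")
    emit(s$cumulative, "cumulative_counts.csv")
    emit(as.list(s$cumulative_stats), "cumulative_stats.json")
    s
  })
  if (!is.null(analyses$cooccur)) stage("cooccur", {
    m <- fit_contemporaneous(panel, catalog)
    emit(tibble::as_tibble(m), "cooccur_adjusted.csv")
    m
  })
  if (!is.null(analyses$lag1)) stage("lag1", {
    m <- fit_lag1(panel, catalog)
    emit(tibble::as_tibble(m), "cooccur_lag1.csv")
    m
  })
  if (!is.null(analyses$autocorrelation)) stage("autocorrelation", {
    f <- fit_autocorrelation(panel)
    emit(glmm_estimates(f, natural = TRUE), "autocorrelation.csv")
    f
  })
  if (!is.null(analyses$accumulation)) stage("accumulation", {
    win <- if (is.list(analyses$accumulation))
      analyses$accumulation$window %||% 20 else 20
    wp <- consecutive_window(panel, min(win, length(unique(panel$year))))
    cmp <- compare_accumulation(wp, catalog)
    emit(cmp$comparison, "accumulation_comparison.csv")
    emit(do.call(rbind, lapply(names(cmp$fits), function(nm) {
      f <- cmp$fits[[nm]]
      tibble::tibble(model = nm, loglik = f$loglik, df = f$df,
                     AIC = f$AIC, BIC = f$BIC)
    })), "accumulation_fits.csv")
    cmp
  })
  if (!is.null(analyses$tailfit)) stage("tailfit", {
    dists <- if (is.list(analyses$tailfit))
      analyses$tailfit$distributions %||%
        c("powerlaw", "exponential", "lognormal", "poisson")
    else c("powerlaw", "exponential", "lognormal", "poisson")
    cum <- count_summaries(panel)$cumulative
    x <- exclude_zeros(cum$total)
    fits <- lapply(dists, function(d) {
      est <- estimate_xmin(x, d)
      est$fit
    })
    names(fits) <- dists
    vt <- NULL
    if ("lognormal" %in% dists) {
      others <- setdiff(dists, "lognormal")
      vt <- lapply(others, function(d)
        vuong_compare(fits[["lognormal"]], fits[[d]], x))
      names(vt) <- others
    }
    emit(list(
      fits = lapply(fits, function(f)
        list(distribution = f$distribution, pars = as.list(f$pars),
             xmin = f$xmin, ks = f$ks, n_tail = f$n_tail,
             loglik = f$loglik,
             dialect = if (f$discrete) "discrete" else "continuous")),
      vuong = lapply(vt, function(v)
        list(statistic = v$statistic, p = v$p_value, xmin = v$xmin))),
      "tailfit.json")
    fits
  })

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$output_md5 <- as.list(
    tools::md5sum(file.path(out_dir, manifest$outputs)))
  names(manifest$output_md5) <- manifest$outputs
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

resolve_catalog <- function(x) {
  if (is.null(x)) return(catalog_swiss())
  if (is.character(x))
    return(switch(x, swiss = catalog_swiss(),
                  australia = catalog_australia(),
                  stop_ale("unknown catalog '%s'", x)))
  ale_catalog(x$events, x$exclusivity_groups %||% list(),
              x$reference %||% NULL)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
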