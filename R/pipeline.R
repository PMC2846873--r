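# End-to-end pipeline: raw tables -> prepared views -> classified views ->
# median-life summaries, usage metrics, crosstabs, aging fits and rankings.

#' Build a validated pipeline run configuration
#'
#' @param input directory with the five cohort CSVs, or an in-memory named
#'   list of tables (e.g. a [generate_cohort()] result).
#' @param out output directory; `NULL` keeps results in memory only.
#' @param mode version handling: `"grouped"` (information-centric) or
#'   `"all"` (file-centric).
#' @param stratifiers median-life stratifiers to compute.
#' @param window_months number of trailing calendar months of views used as
#'   aging-model fitting windows (one fit per month).
#' @param max_age_months largest monthly age bin.
#' @param dev_users development logins to exclude; `NULL` takes the
#'   `is_dev` flag from the sessions table.
#' @param seed integer seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, out = NULL, mode = c("grouped", "all"),
                       stratifiers = c("department",
                                       "creation_encounter_type",
                                       "icd9_chapter", "sex", "age_group"),
                       window_months = 4L, max_age_months = 44L,
                       dev_users = NULL, seed = 1L) {
  mode <- match.arg(mode)
  bad <- setdiff(stratifiers, .stratifiers)
  if (length(bad)) {
    rl_stop(sprintf("unknown stratifier(s): %s; valid options: %s",
                    paste(bad, collapse = ", "),
                    paste(.stratifiers, collapse = ", ")),
            "reportlife_usage_error")
  }
  if (window_months < 1L || max_age_months < 3L) {
    rl_stop("window_months must be >= 1 and max_age_months >= 3",
            "reportlife_config_error")
  }
  structure(list(input = input, out = out, mode = mode,
                 stratifiers = stratifiers,
                 window_months = as.integer(window_months),
                 max_age_months = as.integer(max_age_months),
                 dev_users = dev_users, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Validates the input tables, prepares the view log (development-session
#' exclusion, duration inference, mistaken-view filtering, version
#' grouping), classifies every view's encounter context, and computes the
#' stratified median-life summaries, usage-evolution metrics, the
#' creation-by-view quarter crosstab, the setting crosstab, per-month aging
#' model fits (both families) with a model comparison, and a
#' threshold-mode report ranking at the end of the observation period.
#' Rerunning on identical inputs reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly when writing to disk) a named list bundle:
#'   `validation`, `prepared` summary, `classified` views, `median_life`
#'   (one table per stratifier), `usage`, `creation_view`, `setting`,
#'   `series`, `fits`, `model_comparison`, `ranking`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    rl_stop("config must be a run_config object", "reportlife_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, reportlife_error = function(e) {
      rl_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), class(e)[1L])
    })
  }

  lv <- stage("load_and_validate", load_and_validate(config$input))
  tb <- lv$tables

  prep <- stage("prepare", prepare_views(
    tb$sessions, tb$views, tb$reports, dev_users = config$dev_users,
    mode = config$mode))

  classified <- stage("classify", classify_views(prep$views, tb$encounters))

  median_life_tabs <- lapply(config$stratifiers, function(s) {
    stage(paste0("stats:", s), stratified_median_life(
      classified, s, patients = tb$patients))
  })
  names(median_life_tabs) <- config$stratifiers

  usage <- stage("usage_evolution",
                 usage_evolution(prep$sessions, prep$views, tb$encounters))
  crosstab <- stage("creation_view_crosstab",
                    creation_view_crosstab(prep$views, tb$reports))
  setting <- stage("setting_crosstab", setting_crosstab(classified))

  # aging model: one fit per trailing calendar month of view activity
  classified[, view_month := format(as_utc(request_time), "%Y-%m")]
  months <- sort(unique(classified$view_month))
  months <- utils::tail(months, config$window_months)
  series <- list(); fits <- list()
  for (m in months) {
    ages <- classified[view_month == m, report_age_days]
    if (length(ages) < 50L) next  # too thin a window to fit
    s <- suppressMessages(bin_view_ages(ages, config$max_age_months,
                                        window = m))
    if (sum(s$y > 0) < 3L) next
    series[[m]] <- s
    fits[[paste0(m, ":exponential")]] <- suppressWarnings(fit_exponential(s))
    fits[[paste0(m, ":logarithmic")]] <- suppressWarnings(fit_logarithmic(s))
  }
  comparison <- if (length(fits)) compare_models(fits) else NULL

  # threshold-mode ranking of every report group at end of observation
  ref_time <- max(as_utc(classified$request_time))
  dept_med <- median_life_tabs[["department"]]
  ranking <- NULL
  if (!is.null(dept_med) && nrow(dept_med)) {
    groups <- prep$groups[department %in% dept_med$stratum]
    rank_in <- groups[, .(report_id = group_id, department,
                          available_at = first_available,
                          age_days = diff_days(ref_time, first_available))]
    med_lookup <- as.list(stats::setNames(dept_med$median_life,
                                          dept_med$stratum))
    ranking <- stage("rank", rank_reports(rank_in, dept_medians = med_lookup))
  }

  bundle <- list(
    validation = lv$report,
    prepared = prep$summary,
    classified = classified,
    median_life = median_life_tabs,
    usage = usage,
    creation_view = crosstab,
    setting = setting,
    series = series,
    fits = fits,
    model_comparison = comparison,
    ranking = ranking,
    provenance = list(
      package = "reportlife",
      version = as.character(utils::packageVersion("reportlife")),
      mode = config$mode,
      stratifiers = config$stratifiers,
      window_months = config$window_months,
      max_age_months = config$max_age_months,
      seed = config$seed,
      row_counts = lapply(tb, nrow)
    )
  )
  if (!is.null(config$out)) {
    write_bundle(bundle, config$out)
    return(invisible(bundle))
  }
  bundle
}

fit_to_list <- function(f) {
  list(family = f$family, params = as.list(f$params), r2 = f$r2,
       n_points = f$n_points)
}

#' Write a pipeline bundle to disk
#'
#' CSV for tabular outputs, JSON for summaries, fits and provenance.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(dt, name) {
    if (!is.null(dt) && nrow(data.table::as.data.table(dt))) {
      dt <- data.table::copy(data.table::as.data.table(dt))
      for (col in names(dt)) {
        if (inherits(dt[[col]], "POSIXct")) {
          data.table::set(dt, j = col,
                          value = format(dt[[col]], "%Y-%m-%dT%H:%M:%OS3",
                                         tz = "UTC"))
        }
        if (is.list(dt[[col]])) data.table::set(dt, j = col, value = NULL)
      }
      data.table::fwrite(dt, file.path(dir, paste0(name, ".csv")))
    }
  }
  w(bundle$validation, "validation")
  w(bundle$classified, "classified_views")
  for (s in names(bundle$median_life)) {
    w(bundle$median_life[[s]], paste0("median_life_", s))
  }
  w(bundle$usage, "usage_evolution")
  if (!is.null(bundle$creation_view)) {
    w(bundle$creation_view$counts, "creation_view_counts")
    w(bundle$creation_view$pct_previous, "creation_view_pct_previous")
  }
  w(bundle$setting, "setting_crosstab")
  w(bundle$ranking, "ranking")
  jsonlite::write_json(
    list(prepared = bundle$prepared,
         fits = lapply(bundle$fits, fit_to_list),
         model_comparison = bundle$model_comparison,
         provenance = bundle$provenance),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
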