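# Median-life statistics: report ages, median/quartile summaries by stratum,
# patient age groups, usage-evolution metrics, creation-by-view crosstabs and
# empirical aging (survival) curves.

#' Report age in days
#'
#' Time elapsed between a report being made available and it being viewed,
#' in fractional days.
#'
#' @param view_time,availability_time timestamps (vectors recycle).
#' @return numeric days.
#' @export
report_age <- function(view_time, availability_time) {
  diff_days(view_time, availability_time)
}

#' Median life of a set of view ages
#'
#' The median life is the report age by which half of the views have
#' occurred: the sample median of per-view ages. Quartiles use linear
#' interpolation between order statistics (R quantile type 7). The
#' dispersion ratio is p75/p25.
#'
#' @param ages nonempty numeric vector of ages in days.
#' @return a list of class `median_life_summary`: `n_views`, `median_life`,
#'   `p25`, `p75`, `dispersion_ratio` (days).
#' @export
median_life <- function(ages) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0L) {
    rl_stop("cannot summarise an empty stratum", "reportlife_empty_stratum")
  }
  q <- unname(stats::quantile(ages, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n_views = length(ages), median_life = q[2L],
                 p25 = q[1L], p75 = q[3L],
                 dispersion_ratio = if (q[1L] > 0) q[3L] / q[1L] else NA_real_),
            class = "median_life_summary")
}

#' @export
print.median_life_summary <- function(x, ...) {
  cat(sprintf(
    "Median life: %.1f days (p25 %.1f, p75 %.1f) over %d views\n",
    x$median_life, x$p25, x$p75, x$n_views))
  invisible(x)
}

#' Patient age-group label
#'
#' Bins: child 0-12, teenager 13-19, young adult 20-34, adult 35-54,
#' old adult 55-69, senior 70 and above (exactly 70 is assigned to senior;
#' the source binning leaves it unstated).
#'
#' @param age_years nonnegative ages in whole years.
#' @return character vector of labels.
#' @export
assign_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) {
    rl_stop("age_years must be nonnegative", "reportlife_parameter_error")
  }
  cut(age_years, breaks = c(-Inf, 12, 19, 34, 54, 69, Inf),
      labels = c("child", "teenager", "young adult", "adult", "old adult",
                 "senior")) |> as.character()
}

.stratifiers <- c("sex", "age_group", "department",
                  "creation_encounter_type", "icd9_chapter", "icd9_section")

#' Stratified median-life summaries
#'
#' Computes one [median_life()] summary per stratum of classified views.
#' ICD-9 strata are restricted to views of reports produced in inpatient
#' encounters (only those carry a main diagnosis); for `icd9_section`,
#' strata with `min_views` (default 20) or fewer views are suppressed.
#' Patient age is taken at the report's availability date.
#'
#' @param classified_views output of [classify_views()].
#' @param stratifier one of `r paste0('"', .stratifiers, '"', collapse = ", ")`.
#' @param patients patients table (needed for `sex` and `age_group`).
#' @param min_views suppression threshold for `icd9_section` strata.
#' @return a `data.table` with `stratum`, `n_views`, `median_life`, `p25`,
#'   `p75`, `dispersion_ratio`, sorted by decreasing median life.
#' @export
stratified_median_life <- function(classified_views, stratifier,
                                   patients = NULL, min_views = 20L) {
  if (!is.character(stratifier) || length(stratifier) != 1L ||
      !stratifier %in% .stratifiers) {
    rl_stop(sprintf("unknown stratifier '%s'; valid options: %s",
                    paste(stratifier, collapse = ","),
                    paste(.stratifiers, collapse = ", ")),
            "reportlife_usage_error")
  }
  cv <- data.table::as.data.table(classified_views)
  stopifnot_cols(cv, c("report_age_days", "patient_id"), "classified_views")
  cv <- data.table::copy(cv)

  if (stratifier %in% c("sex", "age_group")) {
    if (is.null(patients)) {
      rl_stop(sprintf("stratifier '%s' needs the patients table", stratifier),
              "reportlife_usage_error")
    }
    pt <- data.table::as.data.table(patients)
    stopifnot_cols(pt, c("patient_id", "sex", "birth_date"), "patients")
    cv[pt, `:=`(sex = i.sex, birth_date = i.birth_date), on = "patient_id"]
  }

  stratum <- switch(
    stratifier,
    sex = cv$sex,
    age_group = {
      age_years <- floor(as.numeric(
        utc_date(cv$anchor %||% cv$request_time) -
          as.Date(cv$birth_date)) / 365.25)
      assign_age_group(pmax(age_years, 0))
    },
    department = cv$department,
    creation_encounter_type = cv$producing_type,
    icd9_chapter = {
      cv <- cv[producing_type == "inpatient" & !is.na(main_dx)]
      icd9_chapter(cv$main_dx)
    },
    icd9_section = {
      cv <- cv[producing_type == "inpatient" & !is.na(main_dx)]
      icd9_section(cv$main_dx)
    }
  )
  cv[, stratum := stratum]
  cv <- cv[!is.na(stratum)]
  out <- cv[, {
    s <- median_life(report_age_days)
    list(n_views = s$n_views, median_life = s$median_life, p25 = s$p25,
         p75 = s$p75, dispersion_ratio = s$dispersion_ratio)
  }, by = stratum]
  if (stratifier == "icd9_section") out <- out[n_views > min_views]
  data.table::setorder(out, -median_life)
  out[]
}

#' Usage-evolution metrics by calendar quarter
#'
#' Groups activity by calendar quarter of session start and reports session,
#' view (all versions), distinct-user (distinct logins) and distinct-computer
#' (distinct IPs) counts, plus views per session, per encounter, per user,
#' and per user per 10,000 encounters, computed as
#' `(views / distinct users) / encounters * 10000`. Quarters with zero users
#' report `NA` for per-user metrics.
#'
#' @param sessions,views prepared (development-free) log tables.
#' @param encounters encounters table; an encounter is counted in the quarter
#'   of its start.
#' @return a `data.table`, one row per quarter.
#' @export
usage_evolution <- function(sessions, views, encounters) {
  se <- data.table::as.data.table(sessions)
  vi <- data.table::as.data.table(views)
  en <- data.table::as.data.table(encounters)
  stopifnot_cols(se, c("session_id", "login", "ip", "start"), "sessions")
  stopifnot_cols(vi, c("view_id", "session_id"), "views")
  stopifnot_cols(en, c("encounter_id", "start"), "encounters")
  se <- data.table::copy(se)[, quarter := quarter_label(start)]
  vi <- data.table::copy(vi)
  vi[se, quarter := i.quarter, on = "session_id"]
  enq <- en[, .(n_encounters = .N), by = .(quarter = quarter_label(start))]

  sq <- se[, .(n_sessions = .N,
               distinct_users = data.table::uniqueN(login),
               distinct_computers = data.table::uniqueN(ip)), by = quarter]
  vq <- vi[!is.na(quarter), .(n_views = .N), by = quarter]
  out <- merge(sq, vq, by = "quarter", all = TRUE)
  out <- merge(out, enq, by = "quarter", all.x = TRUE)
  for (col in c("n_sessions", "n_views", "distinct_users",
                "distinct_computers", "n_encounters")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, views_per_session := ifelse(n_sessions > 0, n_views / n_sessions,
                                    NA_real_)]
  out[, views_per_encounter := ifelse(n_encounters > 0,
                                      n_views / n_encounters, NA_real_)]
  out[, views_per_user := ifelse(distinct_users > 0,
                                 n_views / distinct_users, NA_real_)]
  out[, views_per_user_per_10k_encounters :=
        ifelse(distinct_users > 0 & n_encounters > 0,
               (n_views / distinct_users) / n_encounters * 1e4, NA_real_)]
  data.table::setorder(out, quarter)
  out[]
}

#' Crosstab of views by quarter of report creation and quarter of view
#'
#' @param views views table with `request_time` and `report_id`.
#' @param reports reports table supplying each report's `available_at`
#'   (creation) timestamp.
#' @return list with `counts` (a `data.table` matrix: rows = creation
#'   quarter, columns = view quarters) and `pct_previous` (per view quarter,
#'   the percentage of views whose report was created in an earlier quarter:
#'   `100 * (1 - diagonal / column total)`).
#' @export
creation_view_crosstab <- function(views, reports) {
  vi <- data.table::as.data.table(views)
  re <- data.table::as.data.table(reports)
  stopifnot_cols(vi, c("report_id", "request_time"), "views")
  stopifnot_cols(re, c("report_id", "available_at"), "reports")
  vi <- data.table::copy(vi)
  vi[re, available_at := i.available_at, on = "report_id"]
  if (anyNA(vi$available_at)) {
    rl_stop("view references a report with no creation timestamp",
            "reportlife_integrity_error")
  }
  if (any(as_utc(vi$available_at) > as_utc(vi$request_time) + 1)) {
    rl_stop("report created after it was viewed", "reportlife_integrity_error")
  }
  vi[, `:=`(creation_quarter = quarter_label(available_at),
            view_quarter = quarter_label(request_time))]
  counts <- data.table::dcast(
    vi[, .N, by = .(creation_quarter, view_quarter)],
    creation_quarter ~ view_quarter, value.var = "N", fill = 0L)
  vq <- setdiff(names(counts), "creation_quarter")
  pct_previous <- vapply(vq, function(q) {
    total <- sum(counts[[q]])
    same <- counts[creation_quarter == q][[q]]
    if (length(same) == 0L) same <- 0L
    if (total == 0) NA_real_ else 100 * (1 - same / total)
  }, numeric(1))
  list(counts = counts[],
       pct_previous = data.table::data.table(view_quarter = vq,
                                             pct_previous = pct_previous))
}

#' Empirical aging (survival) curves by report-creation encounter type
#'
#' For each producing encounter type, the fraction of views whose report age
#' is at least `t`, evaluated on a common age grid -- the empirical
#' complement of the view-age distribution. The curve's 50% crossing is the
#' type's median life.
#'
#' @param classified_views output of [classify_views()].
#' @param by column to stratify curves by (default `"producing_type"`).
#' @param grid_days optional age grid; defaults to 200 points spanning the
#'   observed ages.
#' @return a `data.table` with `type`, `age_days`, `survival` (non-increasing
#'   per type), plus attribute `"medians"` mapping type to its median life.
#' @export
aging_curve <- function(classified_views, by = "producing_type",
                        grid_days = NULL) {
  cv <- data.table::as.data.table(classified_views)
  stopifnot_cols(cv, c("report_age_days", by), "classified_views")
  cv <- cv[!is.na(get(by))]
  if (nrow(cv) == 0L) {
    rl_stop("no views to build aging curves from", "reportlife_empty_stratum")
  }
  if (is.null(grid_days)) {
    grid_days <- seq(0, max(cv$report_age_days), length.out = 200L)
  }
  out <- cv[, {
    ages <- report_age_days
    list(age_days = grid_days,
         survival = vapply(grid_days, function(t) mean(ages >= t),
                           numeric(1)))
  }, by = .(type = get(by))]
  medians <- cv[, stats::quantile(report_age_days, 0.5, type = 7),
                by = .(type = get(by))]
  data.table::setattr(out, "medians",
                      stats::setNames(medians$V1, medians$type))
  out[]
}
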