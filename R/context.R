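# Encounter-context inference: which hospital encounter was a report viewed
# in, and how does that encounter relate to the encounter that produced the
# report (concomitant/present, last, previous)?

.point_types <- c("outpatient", "emergency", "day-care", "lab-result",
                  "radiology")

# Normalise an encounters table: UTC timestamps plus calendar-day bounds.
# Inpatient stays match any day of the closed interval [start, end]; the
# other types are single-day events matching on calendar-date equality.
.enc_days <- function(encounters) {
  enc <- data.table::as.data.table(encounters)
  stopifnot_cols(enc, c("encounter_id", "patient_id", "type", "start", "end"),
                 "encounters")
  enc <- data.table::copy(enc)
  enc[, `:=`(start = as_utc(start), end = as_utc(end))]
  if (any(enc$end < enc$start)) {
    rl_stop("encounter with end before start", "reportlife_integrity_error")
  }
  if (!"main_dx" %in% names(enc)) enc[, main_dx := NA_character_]
  enc[, day_lo := as.integer(utc_date(start))]
  enc[, day_hi := data.table::fifelse(type == "inpatient",
                                      as.integer(utc_date(end)), day_lo)]
  enc[, is_interval := type == "inpatient"]
  enc
}

#' Find the encounter a view belongs to
#'
#' Compares the calendar date of the view with the patient's encounter dates.
#' An inpatient stay matches when the view date falls inside the closed
#' interval of the stay; single-day encounter types match on calendar-date
#' equality. When several encounters match, an inpatient interval beats
#' point encounters, then the latest-starting encounter wins. When nothing
#' matches, no assumption is made (`NULL`).
#'
#' @param view_time a single timestamp.
#' @param patient_encounters encounters of exactly one patient.
#' @return the matching encounter as a one-row `data.table`, or `NULL`.
#' @export
encounter_at <- function(view_time, patient_encounters) {
  enc <- .enc_days(patient_encounters)
  if (data.table::uniqueN(enc$patient_id) > 1L) {
    rl_stop("encounter_at expects encounters from a single patient",
            "reportlife_integrity_error")
  }
  d <- as.integer(utc_date(view_time))
  hit <- enc[day_lo <= d & day_hi >= d]
  if (nrow(hit) == 0L) return(NULL)
  data.table::setorder(hit, -is_interval, -start, encounter_id)
  hit[1L, !c("day_lo", "day_hi", "is_interval")]
}

#' Classify a view's relation to the report's producing encounter
#'
#' `present`: the report was produced in the encounter the view belongs to.
#' `last`: it was produced in the patient's immediately preceding encounter
#' (whatever its type) before the viewing encounter's start. `previous`: it
#' was produced earlier than that. `unmatched`: the view has no encounter
#' context, or the report no producing encounter, or the producing encounter
#' does not belong to the strictly-before history (e.g. a concurrent
#' same-day encounter that lost the tie-break).
#'
#' @param view_time timestamp of the view.
#' @param producing_encounter_id id of the encounter that produced the
#'   report, or `NA`.
#' @param patient_encounters the patient's full encounter history.
#' @return one of `"present"`, `"last"`, `"previous"`, `"unmatched"`.
#' @export
classify_relation <- function(view_time, producing_encounter_id,
                              patient_encounters) {
  enc <- .enc_days(patient_encounters)
  ev <- encounter_at(view_time, patient_encounters)
  if (is.null(ev) || is.na(producing_encounter_id) ||
      !producing_encounter_id %in% enc$encounter_id) {
    return("unmatched")
  }
  if (identical(ev$encounter_id, producing_encounter_id)) return("present")
  p_start <- enc[encounter_id == producing_encounter_id, start]
  if (p_start > as_utc(view_time)) {
    rl_stop("report produced after the view (future report)",
            "reportlife_integrity_error")
  }
  before <- enc[start < ev$start, start]
  if (length(before) == 0L || !(p_start < ev$start)) return("unmatched")
  if (p_start == max(before)) "last" else "previous"
}

#' Classify prepared views against patient encounter histories
#'
#' Vectorised composition of [encounter_at()] and [classify_relation()] over
#' a prepared view table, adding the report age relative to the prepared
#' anchor (group first availability in grouped mode, version availability in
#' all-versions mode).
#'
#' @param prepared_views the `views` table from [prepare_views()] (needs
#'   `patient_id`, `request_time`, `anchor`, `producing_encounter_id`).
#' @param encounters full encounters table.
#' @return a classified-view `data.table` adding `encounter_at_id`,
#'   `encounter_at_type`, `relation`, `producing_type`, `main_dx` (of the
#'   producing encounter) and `report_age_days`.
#' @export
classify_views <- function(prepared_views, encounters) {
  v <- data.table::as.data.table(prepared_views)
  stopifnot_cols(v, c("patient_id", "request_time", "anchor",
                      "producing_encounter_id"), "prepared_views")
  v <- data.table::copy(v)
  v[, request_time := as_utc(request_time)]
  v[, anchor := as_utc(anchor)]
  v[, report_age_days := diff_days(request_time, anchor)]
  if (any(v$report_age_days < -1e-9)) {
    rl_stop("view earlier than report availability (check upstream anchors)",
            "reportlife_integrity_error")
  }
  enc <- .enc_days(encounters)
  # strictly-previous start per encounter (max start < own start, per patient)
  enc[, prev_strict_start := {
    us <- sort(unique(start))
    pos <- match(start, us)
    out <- as.POSIXct(rep(NA_real_, .N), tz = "UTC",
                      origin = "1970-01-01")
    out[pos > 1L] <- us[pos[pos > 1L] - 1L]
    out
  }, by = patient_id]

  v[, view_day := as.integer(utc_date(request_time))]
  v[, row_id := .I]
  cand <- enc[v[, .(row_id, patient_id, view_day)],
              on = .(patient_id, day_lo <= view_day, day_hi >= view_day),
              allow.cartesian = TRUE, nomatch = NULL,
              .(row_id, encounter_id, type, start, is_interval,
                prev_strict_start)]
  data.table::setorder(cand, row_id, -is_interval, -start, encounter_id)
  best <- cand[!duplicated(row_id)]
  v[best, `:=`(encounter_at_id = i.encounter_id,
               encounter_at_type = i.type,
               ev_start = i.start,
               ev_prev_start = i.prev_strict_start),
    on = "row_id"]

  v[enc, `:=`(producing_type = i.type, p_start = i.start, main_dx = i.main_dx),
    on = c(producing_encounter_id = "encounter_id")]
  if (any(!is.na(v$p_start) & v$p_start > v$request_time)) {
    rl_stop("report produced after its view (future report)",
            "reportlife_integrity_error")
  }
  rel <- rep("unmatched", nrow(v))
  resolved <- !is.na(v$encounter_at_id) & !is.na(v$producing_encounter_id) &
    !is.na(v$p_start)
  rel[resolved & v$producing_encounter_id == v$encounter_at_id] <- "present"
  earlier <- resolved & v$producing_encounter_id != v$encounter_at_id &
    v$p_start < v$ev_start
  # p_start < ev_start implies ev_prev_start exists and p_start <= it
  rel[earlier & v$p_start == v$ev_prev_start] <- "last"
  rel[earlier & v$p_start < v$ev_prev_start] <- "previous"
  v[, relation := rel]
  v[, c("view_day", "row_id", "ev_start", "ev_prev_start", "p_start") := NULL]
  v[]
}

#' Crosstab of viewing setting by report-creation setting
#'
#' For each viewing setting (rows), the percentage of views whose report was
#' produced in the present encounter, in the last encounter (split by the
#' producing encounter's type), or in any previous encounter (same split).
#' Percentages are row percentages and sum to 100 up to rounding; unmatched
#' views are excluded.
#'
#' @param classified_views output of [classify_views()].
#' @param viewed_in viewing settings to report rows for.
#' @param producing_types producing-encounter types to split the last /
#'   previous columns by; everything else is pooled into `"other"`.
#' @return a `data.table`, one row per viewing setting, with `n`, `present`,
#'   `last_<type>`/`last_total` and `previous_<type>`/`previous_total`
#'   percentage columns. Empty input yields an empty table.
#' @export
setting_crosstab <- function(classified_views,
                             viewed_in = c("emergency", "inpatient",
                                           "outpatient"),
                             producing_types = c("emergency", "inpatient",
                                                 "outpatient")) {
  cv <- data.table::as.data.table(classified_views)
  if (nrow(cv) == 0L) return(data.table::data.table())
  stopifnot_cols(cv, c("relation", "encounter_at_type", "producing_type"),
                 "classified_views")
  cv <- cv[relation != "unmatched" & encounter_at_type %in% viewed_in]
  if (nrow(cv) == 0L) return(data.table::data.table())
  cv[, ptype := data.table::fifelse(producing_type %in% producing_types,
                                    producing_type, "other")]
  out <- data.table::rbindlist(lapply(viewed_in, function(setting) {
    rows <- cv[encounter_at_type == setting]
    n <- nrow(rows)
    if (n == 0L) return(NULL)
    cell <- function(rel, pt) 100 * sum(rows$relation == rel &
                                          rows$ptype == pt) / n
    rec <- list(viewed_in = setting, n = n,
                present = 100 * sum(rows$relation == "present") / n)
    for (pt in c(producing_types, "other")) {
      rec[[paste0("last_", pt)]] <- cell("last", pt)
    }
    rec$last_total <- 100 * sum(rows$relation == "last") / n
    for (pt in c(producing_types, "other")) {
      rec[[paste0("previous_", pt)]] <- cell("previous", pt)
    }
    rec$previous_total <- 100 * sum(rows$relation == "previous") / n
    data.table::as.data.table(rec)
  }))
  out[]
}
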