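# Log preparation: development-session exclusion, maximum-view-duration
# inference, mistaken-view filtering, and report-version grouping.

#' Exclude development-team sessions
#'
#' Removes every session whose login belongs to the development team, and
#' reports how many were removed (attribute `"n_removed"`). An empty
#' `dev_user_list` is a no-op with a warning.
#'
#' @param sessions sessions table with a `login` column.
#' @param dev_user_list character vector of development-team logins.
#' @return the filtered sessions table; attribute `"n_removed"` holds the
#'   count of removed sessions.
#' @export
exclude_dev_sessions <- function(sessions, dev_user_list) {
  sessions <- data.table::as.data.table(sessions)
  stopifnot_cols(sessions, "login", "sessions")
  if (length(dev_user_list) == 0L) {
    warning("empty dev_user_list: no sessions excluded", call. = FALSE)
    kept <- data.table::copy(sessions)
    data.table::setattr(kept, "n_removed", 0L)
    return(kept)
  }
  drop <- sessions$login %in% dev_user_list
  kept <- sessions[!drop]
  data.table::setattr(kept, "n_removed", sum(drop))
  kept
}

#' Infer maximum viewing durations within sessions
#'
#' The system cannot measure how long a report stays open; the upper bound on
#' viewing time is the gap between a report request and the *next* request in
#' the same session. The last event of each session therefore has an
#' undefined (`NA`) duration. A negative gap (clock skew) marks the event
#' invalid; invalid events are flagged, not silently dropped, so the caller
#' controls the partition of raw views into kept / removed-mistaken /
#' removed-invalid.
#'
#' @param views views table with `session_id` and `request_time`; may span
#'   many sessions.
#' @param session_end optional named vector/list mapping `session_id` to a
#'   session-close timestamp used to bound the final view of each session;
#'   by default the final view's duration stays undefined.
#' @return the views table with columns `max_duration` (seconds, `NA` where
#'   undefined) and `valid` (FALSE for negative-gap events).
#' @export
infer_view_durations <- function(views, session_end = NULL) {
  views <- data.table::as.data.table(views)
  stopifnot_cols(views, c("session_id", "request_time"), "views")
  out <- data.table::copy(views)
  out[, request_time := as_utc(request_time)]
  data.table::setorder(out, session_id, request_time)
  out[, max_duration := as.numeric(
    data.table::shift(request_time, type = "lead") - request_time,
    units = "secs"), by = session_id]
  if (!is.null(session_end)) {
    ends <- as_utc(unlist(session_end, use.names = FALSE))
    names(ends) <- names(session_end)
    out[, is_last := seq_len(.N) == .N, by = session_id]
    out[is_last == TRUE & session_id %in% names(ends),
        max_duration := as.numeric(ends[session_id] - request_time,
                                   units = "secs")]
    out[, is_last := NULL]
  }
  out[, valid := is.na(max_duration) | max_duration >= 0]
  n_bad <- sum(!out$valid)
  if (n_bad > 0) {
    message(sprintf(
      "infer_view_durations: %d event(s) with negative gap flagged invalid",
      n_bad))
  }
  out[]
}

#' Filter mistaken (sub-3-second) views
#'
#' A view whose inferred maximum duration did not take more than three
#' seconds is considered a mistaken view and excluded. Views with an
#' undefined duration (the last event of a session) are kept: exclusion is
#' defined only for measurably short views. Invalid (negative-gap) events,
#' if present, are returned in their own bin so that
#' kept + mistaken + invalid partitions the input exactly.
#'
#' @param views views table carrying `max_duration` (and optionally `valid`)
#'   as produced by [infer_view_durations()].
#' @param threshold duration threshold in seconds (default 3).
#' @return list with `kept`, `removed` (mistaken) and `invalid` tables.
#' @export
filter_mistaken_views <- function(views, threshold = 3.0) {
  views <- data.table::as.data.table(views)
  stopifnot_cols(views, "max_duration", "views")
  if (!"valid" %in% names(views)) views <- data.table::copy(views)[, valid := TRUE]
  invalid <- views[valid == FALSE]
  live <- views[valid == TRUE]
  mistaken <- !is.na(live$max_duration) & live$max_duration <= threshold
  list(kept = live[!mistaken], removed = live[mistaken], invalid = invalid)
}

#' Group report versions into logical reports
#'
#' Laboratory systems resend a report as new findings accrue; in
#' information-centric ("grouped versions") analyses all versions sharing a
#' group key count as one report anchored at the *first* version's
#' availability. The file-centric alternative ("all versions") treats each
#' version separately.
#'
#' @param reports reports table (`report_id`, `group_id`, `patient_id`,
#'   `department`, `available_at`, `producing_encounter_id`, `version`).
#' @return list with `groups` (one row per group: `group_id`,
#'   `first_available`, `department`, `patient_id`, `producing_encounter_id`,
#'   `n_versions`, `member_ids`) and `map` (a `data.table` from `report_id`
#'   to `group_id` and the group's `first_available`).
#' @export
group_versions <- function(reports) {
  reports <- data.table::as.data.table(reports)
  stopifnot_cols(reports, c("report_id", "group_id", "patient_id",
                            "department", "available_at"), "reports")
  bad <- reports[, data.table::uniqueN(patient_id), by = group_id][V1 > 1L]
  if (nrow(bad)) {
    rl_stop(sprintf("version group(s) span multiple patients: %s",
                    paste(utils::head(bad$group_id, 5L), collapse = ", ")),
            "reportlife_integrity_error")
  }
  reports <- data.table::copy(reports)
  reports[, available_at := as_utc(available_at)]
  data.table::setorder(reports, group_id, available_at, report_id)
  groups <- reports[, .(
    first_available = available_at[1L],
    department = department[1L],
    patient_id = patient_id[1L],
    producing_encounter_id = producing_encounter_id[1L],
    n_versions = .N,
    member_ids = list(report_id)
  ), by = group_id]
  map <- reports[, .(report_id, group_id)]
  map[groups, first_available := i.first_available, on = "group_id"]
  list(groups = groups, map = map)
}

#' Prepare raw logs for analysis
#'
#' End-to-end preparation stage: drop development-team sessions and their
#' views, infer per-view maximum durations, drop invalid (clock-skew) events,
#' remove mistaken (sub-3-second) views, and attach the report anchor used
#' for age computation -- the viewed version's own availability in
#' `mode = "all"`, or the version group's first availability in
#' `mode = "grouped"`.
#'
#' @param sessions,views,reports raw tables ([table_schemas()]).
#' @param dev_users development-team logins to exclude; defaults to logins
#'   flagged `is_dev` in the sessions table when that column exists.
#' @param mode `"grouped"` (information-centric) or `"all"` (file-centric).
#' @param threshold mistaken-view duration threshold in seconds.
#' @return list with `views` (kept views joined with `group_id`, `anchor`
#'   availability, `department`, `patient_id`, `producing_encounter_id`) and
#'   `summary` (counts of each preparation step, JSON-serialisable).
#' @export
prepare_views <- function(sessions, views, reports, dev_users = NULL,
                          mode = c("grouped", "all"), threshold = 3.0) {
  mode <- match.arg(mode)
  sessions <- data.table::as.data.table(sessions)
  views <- data.table::as.data.table(views)
  if (is.null(dev_users)) {
    dev_users <- if ("is_dev" %in% names(sessions)) {
      unique(sessions$login[sessions$is_dev %in% TRUE])
    } else {
      character(0)
    }
  }
  n_raw_sessions <- nrow(sessions)
  n_raw_views <- nrow(views)
  kept_sessions <- if (length(dev_users)) {
    exclude_dev_sessions(sessions, dev_users)
  } else {
    data.table::setattr(data.table::copy(sessions), "n_removed", 0L)
  }
  n_dev_sessions <- attr(kept_sessions, "n_removed")
  views <- views[session_id %in% kept_sessions$session_id]
  n_dev_views <- n_raw_views - nrow(views)

  views <- infer_view_durations(views)
  parts <- filter_mistaken_views(views, threshold = threshold)
  kept <- parts$kept

  gv <- group_versions(reports)
  rep_dt <- data.table::as.data.table(reports)
  kept[rep_dt, `:=`(patient_id = i.patient_id, department = i.department,
                    producing_encounter_id = i.producing_encounter_id,
                    available_at = i.available_at),
       on = "report_id"]
  kept[gv$map, `:=`(group_id = i.group_id,
                    first_available = i.first_available),
       on = "report_id"]
  kept[, available_at := as_utc(available_at)]
  kept[, anchor := if (mode == "grouped") first_available else available_at]

  list(
    views = kept[],
    sessions = kept_sessions,
    groups = gv$groups,
    summary = list(
      mode = mode,
      n_raw_sessions = n_raw_sessions,
      n_dev_sessions_removed = n_dev_sessions,
      n_raw_views = n_raw_views,
      n_dev_views_removed = n_dev_views,
      n_invalid_removed = nrow(parts$invalid),
      n_mistaken_removed = nrow(parts$removed),
      pct_mistaken = 100 * nrow(parts$removed) /
        max(1L, nrow(parts$removed) + nrow(parts$kept)),
      n_views_kept = nrow(kept),
      n_report_versions = nrow(rep_dt),
      n_report_groups = nrow(gv$groups)
    )
  )
}
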