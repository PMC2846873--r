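# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, full scans) so they stay
# independent of the vectorised implementation paths they check.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# A hand-built one-patient world: encounter history + reports, used by the
# context and longevity tests.
tiny_world <- function() {
  encounters <- data.table::data.table(
    encounter_id = c("E1", "E2", "E3", "E4", "E5"),
    patient_id = "P1",
    type = c("outpatient", "emergency", "inpatient", "outpatient",
             "emergency"),
    start = ts(c("2005-01-10 09:00:00", "2005-02-01 22:00:00",
                 "2005-02-02 08:00:00", "2005-03-15 10:00:00",
                 "2005-05-20 14:00:00")),
    end = ts(c("2005-01-10 11:00:00", "2005-02-01 23:30:00",
               "2005-02-09 12:00:00", "2005-03-15 11:00:00",
               "2005-05-20 16:00:00")),
    main_dx = c(NA, NA, "162.9", NA, NA)
  )
  reports <- data.table::data.table(
    report_id = c("R1", "R2", "R3"),
    group_id = c("G1", "G2", "G3"),
    patient_id = "P1",
    department = c("clinical-pathology", "pathology", "immune-haemotherapy"),
    available_at = ts(c("2005-01-10 10:00:00", "2005-02-03 12:00:00",
                        "2005-03-15 10:30:00")),
    producing_encounter_id = c("E1", "E3", "E4"),
    version = 1L
  )
  list(encounters = encounters, reports = reports)
}

# Random single-patient encounter history of <= max_n encounters; inpatient
# stays are multi-day, other types single-day, non-overlapping.
random_history <- function(max_n = 6L, patient = "PX") {
  n <- sample.int(max_n, 1L)
  starts <- sort(sample.int(400L, n))
  types <- sample(c("inpatient", "outpatient", "emergency", "day-care"),
                  n, replace = TRUE)
  base <- ts("2005-01-01 10:00:00")
  start <- base + starts * 86400
  end <- start + ifelse(types == "inpatient",
                        pmin(sample.int(8L, n, replace = TRUE),
                             c(diff(starts) - 1L, 1000L)) * 86400,
                        3600)
  end <- pmax(end, start)
  data.table::data.table(
    encounter_id = sprintf("%s_E%d", patient, seq_len(n)),
    patient_id = patient, type = types, start = start, end = end,
    main_dx = NA_character_)
}

# Oracle for encounter matching: full scan over encounters, stated rule --
# inpatient matches on closed calendar-day interval, others on date
# equality; interval beats point, then latest start, then encounter_id.
oracle_encounter_at <- function(view_time, enc) {
  d <- as.Date(view_time, tz = "UTC")
  hits <- list()
  for (i in seq_len(nrow(enc))) {
    lo <- as.Date(enc$start[i], tz = "UTC")
    hi <- if (enc$type[i] == "inpatient") as.Date(enc$end[i], tz = "UTC") else lo
    if (d >= lo && d <= hi) hits[[length(hits) + 1L]] <- enc[i]
  }
  if (!length(hits)) return(NA_character_)
  hits <- data.table::rbindlist(hits)
  hits$interval <- hits$type == "inpatient"
  hits <- hits[order(-interval, -as.numeric(start), encounter_id)]
  hits$encounter_id[1L]
}

# Oracle for the relation classification: scan the full ordered history.
oracle_relation <- function(view_time, producing_id, enc) {
  ev <- oracle_encounter_at(view_time, enc)
  if (is.na(ev) || is.na(producing_id) ||
      !producing_id %in% enc$encounter_id) {
    return("unmatched")
  }
  if (ev == producing_id) return("present")
  ev_start <- enc$start[enc$encounter_id == ev]
  p_start <- enc$start[enc$encounter_id == producing_id]
  before <- enc[enc$start < ev_start]
  if (nrow(before) == 0L || !(p_start < ev_start)) return("unmatched")
  before <- before[order(as.numeric(start))]
  if (p_start == max(as.numeric(before$start))) "last" else "previous"
}

# Closed-form simple-regression oracle (normal equations) for y ~ x.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Small default cohort reused by several test files (built once per run).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(n_patients = 400, seed = 2024))
    }
    cache
  }
})
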