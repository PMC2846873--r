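# Table schemas, validated CSV readers/writers and cohort persistence.

#' Declared table schemas
#'
#' The five flat-file tables the pipeline consumes (CSV stand-ins for the
#' hospital's three database schemas): `patients`, `encounters`, `reports`,
#' `sessions`, `views`. Each entry lists required columns, the primary key
#' and foreign keys. All timestamps are ISO-8601, interpreted as UTC.
#'
#' @return named list of schema descriptors.
#' @export
table_schemas <- function() {
  list(
    patients = list(
      columns = c("patient_id", "sex", "birth_date"),
      key = "patient_id", foreign = list()),
    encounters = list(
      columns = c("encounter_id", "patient_id", "type", "start", "end",
                  "main_dx"),
      key = "encounter_id",
      foreign = list(patient_id = "patients")),
    reports = list(
      columns = c("report_id", "group_id", "patient_id", "department",
                  "available_at", "producing_encounter_id", "version"),
      key = "report_id",
      foreign = list(patient_id = "patients",
                     producing_encounter_id = "encounters")),
    sessions = list(
      columns = c("session_id", "login", "ip", "start", "user_category",
                  "is_dev"),
      key = "session_id", foreign = list()),
    views = list(
      columns = c("view_id", "session_id", "report_id", "request_time"),
      key = "view_id",
      foreign = list(session_id = "sessions", report_id = "reports"))
  )
}

.ts_cols <- c("start", "end", "available_at", "request_time")

#' Write a cohort's tables as CSV
#'
#' @param cohort named list of tables (e.g. a [generate_cohort()] result).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(table_schemas())) {
    if (is.null(cohort[[nm]])) next
    dt <- data.table::copy(data.table::as.data.table(cohort[[nm]]))
    for (col in intersect(.ts_cols, names(dt))) {
      if (inherits(dt[[col]], "POSIXct")) {
        data.table::set(dt, j = col,
                        value = format(dt[[col]], "%Y-%m-%dT%H:%M:%OS3",
                                       tz = "UTC"))
      }
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(dt, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Load and validate cohort tables
#'
#' Reads the five CSV tables from `dir` (or accepts an in-memory named list),
#' checks each against [table_schemas()], and collects all violations --
#' duplicate primary keys and unresolvable foreign keys, with row numbers --
#' exhaustively rather than failing at the first. A missing required column
#' is a hard schema error.
#'
#' @param dir directory holding `<table>.csv` files, or a named list of
#'   tables.
#' @param tables which tables to load (default: all five).
#' @return list with `tables` (parsed, timestamps as UTC POSIXct) and
#'   `report` (a `data.table` of violations: `table`, `row`, `column`,
#'   `problem`; zero rows when clean).
#' @export
load_and_validate <- function(dir, tables = names(table_schemas())) {
  schemas <- table_schemas()[tables]
  out <- list()
  for (nm in names(schemas)) {
    if (is.list(dir) && !is.character(dir)) {
      if (is.null(dir[[nm]])) {
        rl_stop(sprintf("table '%s' missing from input list", nm),
                "reportlife_schema_error")
      }
      dt <- data.table::as.data.table(dir[[nm]])
    } else {
      path <- file.path(dir, paste0(nm, ".csv"))
      if (!file.exists(path)) {
        rl_stop(sprintf("input file not found: %s", path),
                "reportlife_schema_error")
      }
      dt <- data.table::fread(path, colClasses = list(
        character = intersect(schemas[[nm]]$columns,
                              c("patient_id", "encounter_id", "report_id",
                                "group_id", "session_id", "view_id", "login",
                                "ip", "sex", "type", "department", "main_dx",
                                "user_category"))))
    }
    stopifnot_cols(dt, schemas[[nm]]$columns, nm)
    for (col in intersect(.ts_cols, names(dt))) {
      if (!inherits(dt[[col]], "POSIXct")) {
        data.table::set(dt, j = col, value = as_utc(dt[[col]]))
      }
    }
    out[[nm]] <- dt
  }
  viol <- list()
  add_viol <- function(table, rows, column, problem) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.table::data.table(
        table = table, row = rows, column = column, problem = problem)
    }
  }
  for (nm in names(schemas)) {
    sc <- schemas[[nm]]
    dt <- out[[nm]]
    add_viol(nm, which(duplicated(dt[[sc$key]])), sc$key,
             "duplicate primary key")
    for (fk in names(sc$foreign)) {
      parent <- sc$foreign[[fk]]
      if (is.null(out[[parent]])) next
      pk <- table_schemas()[[parent]]$key
      bad <- which(!is.na(dt[[fk]]) & !dt[[fk]] %in% out[[parent]][[pk]])
      add_viol(nm, bad, fk, sprintf("unresolvable key into '%s'", parent))
    }
  }
  if (!is.null(out$encounters)) {
    en <- out$encounters
    add_viol("encounters", which(en$end < en$start), "end",
             "end before start")
    add_viol("encounters",
             which(!is.na(en$main_dx) & nzchar(en$main_dx) &
                     en$type != "inpatient"),
             "main_dx", "main diagnosis on non-inpatient encounter")
  }
  report <- if (length(viol)) {
    data.table::rbindlist(viol)
  } else {
    data.table::data.table(table = character(), row = integer(),
                           column = character(), problem = character())
  }
  list(tables = out, report = report)
}
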