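# Synthetic cohort generator: patients, encounters, report versions, sessions
# and view events with known ground truth, emulating the three database
# extracts (patients/reports, access logs, encounters) that the analysis
# expects, so the whole pipeline is testable without hospital data.

.lab_departments <- c("immune-haemotherapy", "clinical-pathology")
.dev_logins <- sprintf("dev%02d", 1:5)

.default_encounter_mix <- c(
  # Encounter volumes scaled from the study hospital's stated totals
  # (~1.58M outpatient, 200k day-care, 842k emergency incl. consultations,
  # 135k inpatient over 3.25 years), with token lab/radiology shares.
  inpatient = 0.049, outpatient = 0.572, emergency = 0.305,
  `day-care` = 0.072, `lab-result` = 0.001, radiology = 0.001
)

.default_dept_mix <- c(
  # View-share proportions of the departmental sources in the study system;
  # the three laboratory feeders dominate (~96% of views).
  `immune-haemotherapy` = 0.41, `clinical-pathology` = 0.29,
  pathology = 0.25, gastroenterology = 0.03, pneumology = 0.008,
  cardiothoracic = 0.005, obstetrics = 0.004, `intensive-care` = 0.002,
  gynaecology = 0.0007, `paediatric-gastroenterology` = 0.0003
)

# Inpatient main-diagnosis pool, spanning all 17 chapters plus V codes.
.dx_pool <- c(
  "008.45", "038.9", "162.9", "153.9", "174.9", "250.00", "282.60",
  "296.20", "345.90", "410.91", "414.01", "486", "428.0", "571.5",
  "574.20", "584.9", "599.0", "650", "707.00", "715.90", "745.5",
  "765.19", "780.60", "820.8", "959.9", "963.0", "V58.11"
)

#' Build a validated simulation configuration
#'
#' Describes the statistical world a [generate_cohort()] run realises:
#' cohort size, calendar span, the encounter-type and departmental-source
#' mixes, the per-stratum view-age law, and the contamination rates the log
#' preparation stage is expected to remove.
#'
#' View ages (time from report availability to view) are controlled per
#' stratum. A stratum key is `"dept:<department>"`, `"enc:<encounter type>"`
#' or `"default"`; department keys take precedence over encounter-type keys.
#' Each stratum follows either
#' \itemize{
#'   \item a point-mass + exponential-tail mixture (`age_mixture_by_stratum`,
#'     entries `list(a =, b =)`): a view has age zero (same-month, in
#'     practice same-day) with probability `1 - a` and otherwise an
#'     exponential age with rate `b` per month, so the survival fraction of
#'     views aged at least `x` months is exactly `a * exp(-b * x)`; or
#'   \item a log-normal law with a prescribed median (`true_median_by_stratum`,
#'     entries in days; `lognormal_sdlog` sets the spread).
#' }
#'
#' @param n_patients number of patients.
#' @param date_span length-2 Date (or coercible) vector, first day and last
#'   day of the simulated period. Must span at least 30 days.
#' @param encounter_type_mix named probabilities over the six encounter types.
#' @param dept_mix named probabilities over departmental sources.
#' @param age_mixture_by_stratum named list of `list(a, b)` mixture specs.
#' @param true_median_by_stratum optional named list of true medians (days);
#'   takes precedence over a mixture spec at the same stratum level.
#' @param lognormal_sdlog log-scale standard deviation used for
#'   `true_median_by_stratum` strata. The default 1.0 keeps the n = 20,000
#'   median standard error near 0.9% so median recovery is testable at 2%;
#'   real view-age spreads are wider (see the methods vignette).
#' @param mistaken_view_rate fraction of all views that are spurious
#'   sub-3-second views (double clicks); in `[0, 1)`.
#' @param dev_session_rate fraction of all sessions that belong to the
#'   development team; in `[0, 1)`.
#' @param encounters_per_patient_lambda,reports_per_encounter_lambda count
#'   specs; each patient has `1 + <draw>` encounters, each encounter
#'   `1 + <draw>` report groups. A count spec is either a Poisson mean or
#'   `list(fixed = k)` for a deterministic count.
#' @param views_per_report_lambda count spec for views per report group
#'   (zero allowed: unread reports).
#' @param version_extra_lambda count spec for additional versions per
#'   laboratory report group (non-laboratory groups are single-version).
#' @param n_users number of distinct (non-development) user logins.
#' @param seed master integer seed; identical configurations produce
#'   identical cohorts.
#' @return an object of class `sim_config`.
#' @seealso [generate_cohort()], [generate_view_ages()]
#' @export
sim_config <- function(n_patients,
                       date_span = c("2005-01-01", "2007-12-31"),
                       encounter_type_mix = .default_encounter_mix,
                       dept_mix = .default_dept_mix,
                       age_mixture_by_stratum =
                         list(default = list(a = 0.5826, b = 0.12)),
                       true_median_by_stratum = NULL,
                       lognormal_sdlog = 1.0,
                       mistaken_view_rate = 0.022,
                       dev_session_rate = 0.006,
                       encounters_per_patient_lambda = 1.5,
                       reports_per_encounter_lambda = 0.3,
                       views_per_report_lambda = 1.3,
                       version_extra_lambda = 2,
                       n_users = 300,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    rl_stop("n_patients must be a positive count", "reportlife_parameter_error")
  }
  date_span <- as.Date(date_span)
  if (length(date_span) != 2L || any(is.na(date_span))) {
    rl_stop("date_span must be two valid dates", "reportlife_config_error")
  }
  if (as.numeric(diff(date_span)) < 30) {
    rl_stop("date_span too short to host the requested encounters (< 30 days)",
            "reportlife_config_error")
  }
  check_mix(encounter_type_mix, "encounter_type_mix")
  check_mix(dept_mix, "dept_mix")
  for (key in names(age_mixture_by_stratum)) {
    spec <- age_mixture_by_stratum[[key]]
    if (is.null(spec$a) || spec$a < 0 || spec$a > 1) {
      rl_stop(sprintf("age mixture '%s': a must lie in [0, 1]", key),
              "reportlife_parameter_error")
    }
    if (is.null(spec$b) || spec$b <= 0) {
      rl_stop(sprintf("age mixture '%s': b must be > 0", key),
              "reportlife_parameter_error")
    }
  }
  for (key in names(true_median_by_stratum)) {
    if (true_median_by_stratum[[key]] <= 0) {
      rl_stop(sprintf("true_median_by_stratum '%s' must be > 0 days", key),
              "reportlife_parameter_error")
    }
  }
  if (mistaken_view_rate < 0 || mistaken_view_rate >= 1) {
    rl_stop("mistaken_view_rate must lie in [0, 1)",
            "reportlife_parameter_error")
  }
  if (dev_session_rate < 0 || dev_session_rate >= 1) {
    rl_stop("dev_session_rate must lie in [0, 1)",
            "reportlife_parameter_error")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    date_span = date_span,
    encounter_type_mix = encounter_type_mix,
    dept_mix = dept_mix,
    age_mixture_by_stratum = age_mixture_by_stratum,
    true_median_by_stratum = true_median_by_stratum,
    lognormal_sdlog = lognormal_sdlog,
    mistaken_view_rate = mistaken_view_rate,
    dev_session_rate = dev_session_rate,
    encounters_per_patient_lambda = encounters_per_patient_lambda,
    reports_per_encounter_lambda = reports_per_encounter_lambda,
    views_per_report_lambda = views_per_report_lambda,
    version_extra_lambda = version_extra_lambda,
    n_users = as.integer(n_users),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw view ages from the point-mass + exponential-tail mixture
#'
#' Ages follow `P(A = 0) = 1 - a`, and conditional on the tail
#' `A ~ Exponential(rate = b)` in months, so the survival fraction obeys
#' `P(A >= x) = a * exp(-b * x)` for `x > 0` -- the functional form the
#' monthly-binned aging model fits downstream.
#'
#' @param n number of ages to draw (>= 1).
#' @param a tail mass in `[0, 1]`: the fraction of views older than zero.
#' @param b exponential decay rate per month (> 0).
#' @param seed integer seed.
#' @return numeric vector of `n` nonnegative ages in months.
#' @examples
#' ages <- generate_view_ages(1000, a = 0.5826, b = 0.12, seed = 1)
#' mean(ages >= 1)  # ~ 0.5826 * exp(-0.12)
#' @export
generate_view_ages <- function(n, a, b, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rl_stop("n must be a positive count", "reportlife_parameter_error")
  }
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    rl_stop("a (tail mass) must lie in [0, 1]", "reportlife_parameter_error")
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    rl_stop("b (decay rate per month) must be > 0",
            "reportlife_parameter_error")
  }
  with_seed(seed, "view_ages", {
    in_tail <- stats::runif(n) < a
    ages <- numeric(n)
    if (any(in_tail)) {
      ages[in_tail] <- stats::rexp(sum(in_tail), rate = b)
    }
    ages
  })
}

# Draw nonnegative counts from a count spec: Poisson mean, or
# list(fixed = k) for a deterministic count.
.draw_count <- function(spec, n) {
  if (is.list(spec)) {
    if (is.null(spec$fixed) || spec$fixed < 0) {
      rl_stop("count spec list must carry a nonnegative $fixed",
              "reportlife_parameter_error")
    }
    rep(as.integer(spec$fixed), n)
  } else {
    stats::rpois(n, spec)
  }
}

# Resolve the age-law spec for each (department, encounter type) pair.
# Priority: dept-level median > dept-level mixture > enc-level median >
# enc-level mixture > default median > default mixture.
.resolve_age_spec <- function(config, dept, enc_type) {
  keys <- c(paste0("dept:", dept), paste0("enc:", enc_type), "default")
  for (key in keys) {
    m <- config$true_median_by_stratum[[key]]
    if (!is.null(m)) {
      return(list(kind = "lognormal", median_days = m,
                  sdlog = config$lognormal_sdlog))
    }
    mx <- config$age_mixture_by_stratum[[key]]
    if (!is.null(mx)) {
      return(list(kind = "mixture", a = mx$a, b = mx$b))
    }
  }
  rl_stop(sprintf(
    "no age law configured for department '%s' / encounter type '%s' and no 'default' stratum",
    dept, enc_type), "reportlife_config_error")
}

# Deterministic per-login IP (one computer per login; no RNG consumed).
.login_ip <- function(login_idx) {
  sprintf("10.%d.%d.%d", login_idx %/% 65536L %% 256L,
          login_idx %/% 256L %% 256L, login_idx %% 256L)
}

#' Generate a synthetic cohort of patients, encounters, reports and view logs
#'
#' Realises the world described by a [sim_config()]: per-patient encounter
#' histories (multi-day inpatient stays, single-day encounters of the other
#' types, non-overlapping within each patient), report versions produced
#' inside their encounters (laboratory sources emit several versions sharing
#' one group key), views placed at group availability plus a stratum-specific
#' sampled age, spurious sub-3-second "double click" views at the configured
#' rate, and development-team sessions at theirs.
#'
#' Draws use per-table, per-variable derived random streams, so the same
#' configuration is byte-reproducible and growing `n_patients` appends
#' patients without re-randomising earlier ones.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: a list of `data.table`s
#'   `patients`, `encounters`, `reports`, `sessions`, `views` (schemas as in
#'   [table_schemas()]), with the generating truth attached as attribute
#'   `"truth"`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' sapply(cohort, nrow)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    rl_stop("config must be a sim_config object", "reportlife_config_error")
  }
  seed <- config$seed
  n <- config$n_patients
  span_start <- as_utc(paste(config$date_span[1], "00:00:00"))
  span_days <- as.numeric(config$date_span[2] - config$date_span[1])

  ## patients ----------------------------------------------------------------
  patients <- data.table::data.table(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(with_seed(seed, "pat.sex", stats::runif(n)) < 0.5, "M", "F"),
    birth_date = config$date_span[1] -
      round(with_seed(seed, "pat.birth", stats::runif(n, 0.2, 85)) * 365.25)
  )

  ## encounters --------------------------------------------------------------
  n_enc <- 1L + with_seed(seed, "enc.count",
                          .draw_count(config$encounters_per_patient_lambda, n))
  total_enc <- sum(n_enc)
  enc_patient <- rep(patients$patient_id, n_enc)
  type_levels <- names(config$encounter_type_mix)
  type_u <- with_seed(seed, "enc.type", stats::runif(total_enc))
  enc_type <- type_levels[findInterval(type_u,
                                       cumsum(config$encounter_type_mix),
                                       left.open = TRUE) + 1L]
  start_day <- with_seed(seed, "enc.startday",
                         stats::runif(total_enc, 0, span_days - 20))
  start_hour <- with_seed(seed, "enc.starthour",
                          stats::runif(total_enc, 8, 18))
  los_days <- with_seed(seed, "enc.los", 1L + stats::rpois(total_enc, 5))
  enc <- data.table::data.table(
    patient_id = enc_patient, type = enc_type,
    start = span_start + round((floor(start_day) * 24 + start_hour) * 3600),
    los = ifelse(enc_type == "inpatient", los_days, 0)
  )
  data.table::setorder(enc, patient_id, start)
  # end: inpatient stays run los whole days (clamped so stays never overlap
  # the patient's next encounter); point encounters close the same day.
  enc[, end := start + ifelse(type == "inpatient", los * 86400, 2 * 3600)]
  enc[, next_start := data.table::shift(start, type = "lead"),
      by = patient_id]
  enc[type == "inpatient" & !is.na(next_start) & end >= next_start,
      end := pmax(start + 3600, next_start - 86400)]
  enc[, next_start := NULL]
  enc[end < start, end := start]
  dx_u <- with_seed(seed, "enc.dx", stats::runif(total_enc))
  enc[, main_dx := NA_character_]
  enc[type == "inpatient",
      main_dx := .dx_pool[ceiling(dx_u[seq_len(sum(type == "inpatient"))] *
                                    length(.dx_pool))]]
  enc[, encounter_id := sprintf("E%07d", .I)]
  enc[, los := NULL]

  ## report groups and versions ---------------------------------------------
  n_grp <- 1L + with_seed(seed, "rep.count",
                          .draw_count(config$reports_per_encounter_lambda,
                                      total_enc))
  total_grp <- sum(n_grp)
  grp <- data.table::data.table(
    group_id = sprintf("G%07d", seq_len(total_grp)),
    patient_id = rep(enc$patient_id, n_grp),
    producing_encounter_id = rep(enc$encounter_id, n_grp),
    enc_type = rep(enc$type, n_grp),
    enc_start = rep(enc$start, n_grp),
    enc_end = rep(enc$end, n_grp)
  )
  dept_levels <- names(config$dept_mix)
  dept_u <- with_seed(seed, "rep.dept", stats::runif(total_grp))
  grp[, department := dept_levels[findInterval(
    dept_u, cumsum(config$dept_mix), left.open = TRUE) + 1L]]
  avail_frac <- with_seed(seed, "rep.avail", stats::runif(total_grp, 0.05, 0.95))
  grp[, first_available := enc_start +
        round(avail_frac * as.numeric(enc_end - enc_start, units = "secs"))]
  extra <- with_seed(seed, "rep.versions",
                     .draw_count(config$version_extra_lambda, total_grp))
  extra[!(grp$department %in% .lab_departments)] <- 0L
  n_versions <- 1L + extra
  reports <- grp[rep(seq_len(total_grp), n_versions)]
  reports[, version := seq_len(.N), by = group_id]
  # later versions appear between first availability and encounter end
  voff_u <- with_seed(seed, "rep.voffset", stats::runif(nrow(reports)))
  reports[, head_room := as.numeric(enc_end - first_available, units = "secs")]
  reports[, available_at := first_available +
            round(ifelse(version == 1L, 0,
                         voff_u * head_room * (version - 1) / n_versions[
                           match(group_id, grp$group_id)]))]
  data.table::setorder(reports, group_id, available_at, version)
  reports[, version := seq_len(.N), by = group_id]
  reports[, report_id := sprintf("R%08d", .I)]

  ## views -------------------------------------------------------------------
  n_views_grp <- with_seed(seed, "view.count",
                           .draw_count(config$views_per_report_lambda,
                                       total_grp))
  views <- grp[rep(seq_len(total_grp), n_views_grp),
               .(group_id, patient_id, department, enc_type, first_available)]
  nv <- nrow(views)
  if (nv == 0L) {
    rl_stop("configuration produced zero views; increase n_patients or rates",
            "reportlife_config_error")
  }
  # per-view age from the stratum's configured law
  spec_key <- paste(views$department, views$enc_type, sep = "\r")
  uniq <- unique(data.table::data.table(department = views$department,
                                        enc_type = views$enc_type))
  specs <- lapply(seq_len(nrow(uniq)), function(i) {
    .resolve_age_spec(config, uniq$department[i], uniq$enc_type[i])
  })
  names(specs) <- paste(uniq$department, uniq$enc_type, sep = "\r")
  u1 <- with_seed(seed, "view.age.u", stats::runif(nv))
  u2 <- with_seed(seed, "view.age.tail", stats::runif(nv))
  z <- with_seed(seed, "view.age.z", stats::rnorm(nv))
  age_days <- numeric(nv)
  for (key in names(specs)) {
    idx <- which(spec_key == key)
    s <- specs[[key]]
    if (s$kind == "mixture") {
      tail_i <- idx[u1[idx] < s$a]
      # same-month mass: spread over the first hours after availability so
      # distinct views never collide on one timestamp (survival at monthly
      # bins x >= 1 is untouched)
      zero_i <- setdiff(idx, tail_i)
      age_days[zero_i] <- (u1[zero_i] - s$a) / max(1 - s$a, 1e-12) * 0.25
      age_days[tail_i] <- (-log(u2[tail_i]) / s$b) * DAYS_PER_MONTH
    } else {
      age_days[idx] <- exp(log(s$median_days) + s$sdlog * z[idx])
    }
  }
  views[, request_time := first_available + round(age_days * 86400)]
  # viewed version: latest version available at view time
  vmap <- reports[, .(group_id, available_at, report_id)]
  data.table::setkey(vmap, group_id, available_at)
  views[, join_time := request_time]
  views <- vmap[views, on = c("group_id", "available_at" = "join_time"),
                roll = Inf]
  views[, available_at := NULL]  # equals request_time; drop the join echo

  ## sessions: one per (login, calendar day with activity) -------------------
  pat_login <- 1L + floor(with_seed(seed, "sess.user", stats::runif(n)) *
                            config$n_users)
  names(pat_login) <- patients$patient_id
  views[, login_idx := pat_login[patient_id]]
  views[, login := sprintf("u%04d", login_idx)]
  views[, day := as.Date(request_time, tz = "UTC")]
  views[, session_key := paste(login, day, sep = "|")]

  # spurious double-click views: a duplicate request 0.5-3 s before a real one
  p_extra <- config$mistaken_view_rate / (1 - config$mistaken_view_rate)
  extra_sel <- with_seed(seed, "view.mistaken", stats::runif(nv)) < p_extra
  gaps <- with_seed(seed, "view.gap", stats::runif(sum(extra_sel), 0.5, 3.0))
  extras <- views[extra_sel]
  extras[, request_time := request_time - gaps]

  all_views <- data.table::rbindlist(list(views, extras), use.names = TRUE)

  sess <- all_views[, .(start = min(request_time),
                        login = login[1L], login_idx = login_idx[1L]),
                    by = session_key]
  data.table::setorder(sess, start, session_key)
  sess[, session_id := sprintf("S%07d", .I)]
  sess[, `:=`(ip = .login_ip(login_idx), user_category = "doctor",
              is_dev = FALSE)]

  ## development-team sessions ----------------------------------------------
  n_real <- nrow(sess)
  n_dev <- round(config$dev_session_rate / (1 - config$dev_session_rate) *
                   n_real)
  if (n_dev > 0) {
    dev_start <- span_start +
      round(with_seed(seed, "dev.start",
                      stats::runif(n_dev, 0, span_days)) * 86400)
    dev_sess <- data.table::data.table(
      session_key = sprintf("dev|%d", seq_len(n_dev)),
      start = dev_start,
      login = .dev_logins[1L + (seq_len(n_dev) - 1L) %% length(.dev_logins)],
      login_idx = 0L,
      session_id = sprintf("S%07d", n_real + seq_len(n_dev)),
      ip = "10.99.99.1", user_category = "developer", is_dev = TRUE
    )
    n_dev_views <- 1L + with_seed(seed, "dev.nviews",
                                  stats::rpois(n_dev, 2))
    dev_rep_idx <- 1L + floor(with_seed(seed, "dev.rep",
                                        stats::runif(sum(n_dev_views))) *
                                nrow(reports))
    dev_views <- data.table::data.table(
      session_key = rep(dev_sess$session_key, n_dev_views),
      report_id = reports$report_id[dev_rep_idx],
      request_time = reports$available_at[dev_rep_idx] +
        round(with_seed(seed, "dev.age",
                        stats::runif(sum(n_dev_views), 0, 30)) * 86400)
    )
    sess <- data.table::rbindlist(list(sess, dev_sess), use.names = TRUE)
    all_views <- data.table::rbindlist(
      list(all_views[, .(session_key, report_id, request_time)], dev_views),
      use.names = TRUE)
  } else {
    all_views <- all_views[, .(session_key, report_id, request_time)]
  }

  all_views[, session_id := sess$session_id[match(session_key, sess$session_key)]]
  data.table::setorder(all_views, session_id, request_time, report_id)
  all_views[, view_id := sprintf("V%08d", .I)]

  cohort <- list(
    patients = patients,
    encounters = enc[, .(encounter_id, patient_id, type, start, end, main_dx)],
    reports = reports[, .(report_id, group_id, patient_id, department,
                          available_at, producing_encounter_id, version)],
    sessions = sess[, .(session_id, login, ip, start, user_category, is_dev)],
    views = all_views[, .(view_id, session_id, report_id, request_time)]
  )
  structure(cohort, class = "synthetic_cohort", truth = list(
    config = config,
    dev_logins = .dev_logins,
    n_base_views = nv,
    n_mistaken_views = sum(extra_sel)
  ))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:\n")
  for (nm in names(x)) cat(sprintf("  %-10s %8d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
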