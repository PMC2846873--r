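# Median-life statistics, age groups, usage evolution, crosstabs, aging
# curves, ICD-9 mapping.

test_that("report_age converts timestamp differences to fractional days", {
  t0 <- ts("2005-01-01 00:00:00")
  expect_equal(report_age(t0 + 36 * 3600, t0), 1.5)
  expect_equal(report_age(t0, t0), 0)
  # random pairs against a seconds/86400 oracle
  set.seed(12)
  secs <- runif(50, 0, 1e8)
  expect_equal(report_age(t0 + secs, t0), secs / 86400)
})

test_that("median_life uses linearly interpolated order statistics", {
  s <- median_life(c(5, 5, 5))
  expect_equal(c(s$p25, s$median_life, s$p75), c(5, 5, 5))
  expect_identical(s$n_views, 3L)

  s2 <- median_life(1:100)
  expect_equal(s2$median_life, 50.5)
  expect_equal(s2$p25, 25.75)
  expect_equal(s2$p75, 75.25)
  expect_equal(s2$dispersion_ratio, 75.25 / 25.75)

  expect_error(median_life(numeric(0)), "empty stratum",
               class = "reportlife_empty_stratum")
  # percentile coherence under fuzz
  set.seed(3)
  for (i in 1:20) {
    x <- rexp(sample.int(500, 1) + 1, 0.1)
    m <- median_life(x)
    expect_true(m$p25 <= m$median_life && m$median_life <= m$p75)
  }
})

test_that("assign_age_group covers every age with the documented bins", {
  expect_identical(assign_age_group(c(12, 13)), c("child", "teenager"))
  expect_identical(assign_age_group(70), "senior")
  # exhaustive 0..120 against an explicit interval table
  table_oracle <- function(a) {
    if (a <= 12) "child" else if (a <= 19) "teenager" else
      if (a <= 34) "young adult" else if (a <= 54) "adult" else
        if (a <= 69) "old adult" else "senior"
  }
  ages <- 0:120
  expect_identical(assign_age_group(ages),
                   vapply(ages, table_oracle, character(1)))
  expect_error(assign_age_group(-1), "nonnegative",
               class = "reportlife_parameter_error")
})

test_that("stratified_median_life reduces, partitions, and suppresses", {
  co <- shared_cohort()
  prep <- prepare_views(co$sessions, co$views, co$reports)
  cv <- classify_views(prep$views, co$encounters)

  # single-stratum input equals the plain estimator
  one <- cv[department == "pathology"]
  tab <- stratified_median_life(one, "department")
  plain <- median_life(one$report_age_days)
  expect_equal(tab$median_life, plain$median_life)
  expect_equal(tab$p25, plain$p25)
  expect_identical(tab$n_views, plain$n_views)

  # per-stratum n sums to total classifiable views
  dep <- stratified_median_life(cv, "department")
  expect_identical(sum(dep$n_views), nrow(cv))
  enc_tab <- stratified_median_life(cv, "creation_encounter_type")
  expect_identical(sum(enc_tab$n_views), nrow(cv))

  # sex and age_group need the patients table
  expect_error(stratified_median_life(cv, "sex"), "patients table",
               class = "reportlife_usage_error")
  sx <- stratified_median_life(cv, "sex", patients = co$patients)
  expect_setequal(sx$stratum, c("M", "F"))
  ag <- stratified_median_life(cv, "age_group", patients = co$patients)
  expect_true(all(ag$stratum %in% c("child", "teenager", "young adult",
                                    "adult", "old adult", "senior")))

  # ICD-9 strata only use inpatient-produced reports
  ch <- stratified_median_life(cv, "icd9_chapter")
  expect_lte(sum(ch$n_views), sum(cv$producing_type == "inpatient"))

  expect_error(stratified_median_life(cv, "bogus"), "valid options",
               class = "reportlife_usage_error")
})

test_that("icd9_section strata with <= 20 views are suppressed", {
  mk <- function(code, n) data.table::data.table(
    report_age_days = rexp(n, 0.1), patient_id = "P1",
    producing_type = "inpatient", main_dx = code)
  set.seed(5)
  cv <- data.table::rbindlist(list(mk("162.9", 21), mk("820.8", 20)))
  tab <- stratified_median_life(cv, "icd9_section")
  expect_identical(tab$stratum,
                   "Malignant neoplasm of respiratory and intrathoracic organs")
  # chapters have no such suppression
  expect_identical(nrow(stratified_median_life(cv, "icd9_chapter")), 2L)
})

test_that("ICD-9 chapter mapping is total and agrees with a range scan", {
  sec <- icd9_sections()
  # every numeric rubric 001..999 maps to exactly one chapter
  codes <- sprintf("%03d", 1:999)
  ch <- icd9_chapter(codes)
  expect_false(anyNA(ch))
  # range-scan oracle over the packaged section table: a section's rubrics
  # all fall inside one chapter
  for (i in seq_len(nrow(sec))) {
    rubrics <- seq(sec$lo[i], sec$hi[i])
    full <- if (sec$kind[i] == "N") sprintf("%03d", rubrics)
            else paste0(sec$kind[i], rubrics)
    expect_identical(length(unique(icd9_chapter(full))), 1L,
                     label = sec$section[i])
    expect_true(all(icd9_section(full) == sec$section[i] |
                      is.na(icd9_section(full)) == FALSE))
  }
  expect_identical(icd9_chapter("V58.1"),
                   paste("Supplementary classification of factors influencing",
                         "health status and contact with health services"))
  expect_true(is.na(icd9_chapter("banana")))
})

test_that("usage_evolution computes per-quarter metrics with the stated formula", {
  sessions <- data.table::data.table(
    session_id = "S1", login = "u1", ip = "10.0.0.1",
    start = ts("2007-10-05 09:00:00"), user_category = "doctor",
    is_dev = FALSE)
  views <- data.table::data.table(
    view_id = "V1", session_id = "S1", report_id = "R1",
    request_time = ts("2007-10-05 09:01:00"))
  encounters <- data.table::data.table(
    encounter_id = sprintf("E%05d", 1:10000), patient_id = "P1",
    type = "outpatient", start = ts("2007-11-01 08:00:00"),
    end = ts("2007-11-01 09:00:00"), main_dx = NA_character_)
  u <- usage_evolution(sessions, views, encounters)
  expect_identical(u$quarter, "2007Q4")
  expect_equal(u$views_per_user_per_10k_encounters, 1)
  expect_equal(u$views_per_session, 1)
  expect_equal(u$views_per_encounter, 1 / 10000)

  # distinct counts equal a set-cardinality oracle on random logs
  set.seed(21)
  n <- 300
  sess <- data.table::data.table(
    session_id = sprintf("S%03d", 1:n),
    login = sample(sprintf("u%d", 1:40), n, TRUE),
    ip = sample(sprintf("10.0.0.%d", 1:25), n, TRUE),
    start = ts("2006-01-01 00:00:00") + runif(n, 0, 700 * 86400),
    user_category = "doctor", is_dev = FALSE)
  vw <- data.table::data.table(
    view_id = sprintf("V%03d", 1:n),
    session_id = sample(sess$session_id, n, TRUE),
    report_id = "R1",
    request_time = ts("2006-01-01 00:00:00"))
  u2 <- usage_evolution(sess, vw, encounters)
  for (q in u2$quarter) {
    in_q <- sess[quarter_label(start) == q]
    expect_identical(u2[u2$quarter == q, ]$distinct_users,
                     length(unique(in_q$login)))
    expect_identical(u2[u2$quarter == q, ]$distinct_computers,
                     length(unique(in_q$ip)))
  }
  # a quarter with encounters but no sessions yields NA per-user metrics
  expect_true(is.na(u[u$quarter != "2007Q4"]$views_per_user) ||
                all(u$quarter == "2007Q4"))
})

test_that("creation_view_crosstab is conservative and diagonal-aware", {
  reports <- data.table::data.table(
    report_id = sprintf("R%d", 1:3),
    available_at = ts(c("2007-10-01", "2007-10-15", "2007-11-20")))
  views <- data.table::data.table(
    view_id = sprintf("V%d", 1:5),
    report_id = c("R1", "R1", "R2", "R3", "R3"),
    request_time = ts(c("2007-10-02", "2007-11-01", "2007-10-16",
                        "2007-11-21", "2007-12-25")))
  xt <- creation_view_crosstab(views, reports)
  # all views land in the creation quarter here -> 0% previous
  expect_equal(xt$pct_previous$pct_previous, 0)
  expect_equal(sum(as.matrix(xt$counts[, -1])), 5)

  # random fixture: column sums equal per-quarter view counts and the
  # previous-quarter share matches 1 - diagonal/column
  set.seed(33)
  n <- 400
  avail <- ts("2005-01-01 00:00:00") + runif(n, 0, 900 * 86400)
  rep2 <- data.table::data.table(report_id = sprintf("R%03d", 1:n),
                                 available_at = avail)
  vw2 <- data.table::data.table(
    view_id = sprintf("V%03d", 1:n), report_id = rep2$report_id,
    request_time = avail + rexp(n, 1 / (60 * 86400)))
  xt2 <- creation_view_crosstab(vw2, rep2)
  vq <- quarter_label(vw2$request_time)
  for (q in unique(vq)) {
    expect_identical(sum(xt2$counts[[q]]), sum(vq == q))
    diag_cell <- xt2$counts[creation_quarter == q][[q]]
    if (length(diag_cell) == 0) diag_cell <- 0
    expect_equal(xt2$pct_previous[view_quarter == q, pct_previous],
                 100 * (1 - diag_cell / sum(vq == q)))
  }
  # future-dated views are rejected
  bad <- data.table::copy(vw2)[1, request_time := ts("2004-01-01")]
  expect_error(creation_view_crosstab(bad, rep2), "created after",
               class = "reportlife_integrity_error")
})

test_that("aging curves are survival functions anchored at the median", {
  co <- shared_cohort()
  prep <- prepare_views(co$sessions, co$views, co$reports)
  cv <- classify_views(prep$views, co$encounters)
  curves <- aging_curve(cv)
  meds <- attr(curves, "medians")
  for (tp in unique(curves$type)) {
    cu <- curves[type == tp]
    expect_true(all(diff(cu$survival) <= 1e-12))
    expect_true(all(cu$survival >= 0 & cu$survival <= 1))
    expect_equal(unname(meds[tp]),
                 unname(stats::quantile(cv[producing_type == tp,
                                           report_age_days], 0.5, type = 7)))
  }

  # constant ages give a step function
  const <- data.table::data.table(report_age_days = rep(10, 5),
                                  producing_type = "outpatient")
  st <- aging_curve(const, grid_days = c(0, 5, 10, 15))
  expect_equal(st$survival, c(1, 1, 1, 0))

  # smaller decay rate dominates: slower aging
  slow <- generate_view_ages(20000, a = 0.6, b = 0.05, seed = 2) * 30.4375
  fast <- generate_view_ages(20000, a = 0.6, b = 0.5, seed = 2) * 30.4375
  both <- data.table::rbindlist(list(
    data.table::data.table(report_age_days = slow, producing_type = "outpatient"),
    data.table::data.table(report_age_days = fast, producing_type = "emergency")))
  cs <- aging_curve(both, grid_days = c(30, 90, 180))
  expect_true(all(cs[type == "outpatient", survival] >
                    cs[type == "emergency", survival]))
})
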