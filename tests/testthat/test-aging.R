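# Aging models: monthly binning, exponential/logarithmic fits, model
# comparison, relevance scoring and ranking.

month_days <- 30.4375

test_that("bin_view_ages computes the monthly survival fraction", {
  # no old views: y = 0 everywhere past the first month
  z <- bin_view_ages(rep(0.5, 100), max_months = 10)
  expect_equal(z$y, rep(0, 10))
  expect_identical(attr(z, "n_views"), 100L)

  # saturation: every view at least 44 months old
  old <- bin_view_ages(rep(45 * month_days, 50), max_months = 44)
  expect_equal(old$y, rep(1, 44))

  # random ages against a brute-force counting oracle at each x
  set.seed(14)
  ages <- rexp(1000, 1 / 120)
  s <- suppressMessages(bin_view_ages(ages, max_months = 44))
  for (x in c(1, 7, 20, 44)) {
    count <- 0
    for (a in ages) if (a / month_days >= x) count <- count + 1
    expect_equal(s$y[s$x == x], count / 1000)
  }
  expect_true(all(diff(s$y) <= 0))
  expect_true(all(s$y >= 0 & s$y <= 1))
  expect_error(bin_view_ages(numeric(0)), "empty",
               class = "reportlife_empty_stratum")
})

test_that("fit_exponential is exact on noiseless model data", {
  x <- 1:44
  s <- data.table::data.table(x = x, y = exp(-x))
  f <- fit_exponential(s)
  expect_equal(f$params[["a"]], 1, tolerance = 1e-12)
  expect_equal(f$params[["b"]], 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  # nls refinement agrees on noiseless data
  fn <- fit_exponential(s, method = "nls")
  expect_equal(fn$params[["a"]], 1, tolerance = 1e-6)
  expect_equal(fn$params[["b"]], 1, tolerance = 1e-6)

  # nonpositive points are dropped with a warning; too few points error
  s2 <- data.table::data.table(x = 1:4, y = c(0.5, 0.2, 0, -0.1))
  expect_warning(expect_error(fit_exponential(s2), "at least 3",
                              class = "reportlife_parameter_error"),
                 "nonpositive")
})

test_that("log-linear OLS matches the normal-equations oracle to 1e-10", {
  set.seed(8)
  for (i in 1:10) {
    x <- 1:30
    y <- 0.6 * exp(-0.13 * x) * exp(rnorm(30, 0, 0.05))
    f <- fit_exponential(data.table::data.table(x = x, y = y))
    o <- oracle_ols(x, log(y))
    expect_equal(f$params[["b"]], -o$slope, tolerance = 1e-10)
    expect_equal(f$params[["a"]], exp(o$intercept), tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("fit_logarithmic is exact on model data and matches its oracle", {
  x <- 1:44
  exact <- data.table::data.table(x = x, y = -0.2 * log(x) + 0.6)
  f <- fit_logarithmic(exact)
  expect_equal(f$params[["c"]], 0.2, tolerance = 1e-12)
  expect_equal(f$params[["d"]], 0.6, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  set.seed(9)
  y <- -0.16 * log(x) + 0.55 + rnorm(44, 0, 0.02)
  fn <- fit_logarithmic(data.table::data.table(x = x, y = y))
  o <- oracle_ols(log(x), y)
  expect_equal(fn$params[["c"]], -o$slope, tolerance = 1e-10)
  expect_equal(fn$params[["d"]], o$intercept, tolerance = 1e-10)
  expect_equal(fn$r2, o$r2, tolerance = 1e-10)

  expect_error(fit_logarithmic(data.table::data.table(x = 0:5, y = 1:6)),
               "x >= 1", class = "reportlife_parameter_error")
})

test_that("bin -> fit -> predict closes on noiseless mixture data", {
  a <- 0.7; b <- 0.15
  s <- data.table::data.table(x = 1:44, y = a * exp(-b * (1:44)))
  f <- fit_exponential(s)
  pred <- f$params[["a"]] * exp(-f$params[["b"]] * s$x)
  expect_lt(max(abs(pred - s$y)), 1e-9)
})

test_that("compare_models aggregates R2 by family", {
  f1 <- fit_exponential(data.table::data.table(x = 1:10, y = exp(-(1:10))))
  f2 <- fit_logarithmic(data.table::data.table(x = 1:10,
                                               y = -0.1 * log(1:10) + 1))
  cmp <- compare_models(list(f1, f2))
  expect_identical(cmp$winner, "tie")  # both exactly 1

  set.seed(10)
  r2s_e <- runif(4, 0.85, 0.95); r2s_l <- runif(4, 0.80, 0.92)
  fits <- c(
    lapply(r2s_e, function(r) structure(list(family = "exponential",
                                             params = c(a = 1, b = 1),
                                             r2 = r, n_points = 44L),
                                        class = "aging_fit")),
    lapply(r2s_l, function(r) structure(list(family = "logarithmic",
                                             params = c(c = 1, d = 1),
                                             r2 = r, n_points = 44L),
                                        class = "aging_fit")))
  cmp2 <- compare_models(fits)
  expect_equal(cmp2$families$exponential$mean_r2, mean(r2s_e))
  expect_equal(cmp2$families$logarithmic$n_r2_above, sum(r2s_l > 0.9))
  expect_identical(cmp2$winner,
                   if (mean(r2s_e) > mean(r2s_l)) "exponential"
                   else "logarithmic")
})

test_that("relevance_score decays with age and honours the threshold rule", {
  fit <- fit_exponential(
    data.table::data.table(x = 1:44, y = 0.5826 * exp(-0.12 * (1:44))))
  # age 0 scores the maximal min(a, 1)
  expect_equal(relevance_score(0, fit = fit)$score, 0.5826, tolerance = 1e-6)
  # direct formula evaluation oracle on random ages
  set.seed(11)
  ages <- runif(50, 0, 1000)
  sc <- relevance_score(ages, fit = fit)$score
  expect_equal(sc, pmin(0.5826 * exp(-0.12 * ages / month_days), 1),
               tolerance = 1e-6)
  # non-increasing in age
  ages_sorted <- sort(ages)
  expect_true(all(diff(relevance_score(ages_sorted, fit = fit)$score) <= 0))

  # threshold mode: a 20-day-old clinical pathology report against a 15-day
  # stratum median is downgraded
  th <- relevance_score(20, median_life_days = 15)
  expect_false(th$highlight)
  expect_true(relevance_score(14, median_life_days = 15)$highlight)

  expect_error(relevance_score(-1, median_life_days = 15), "nonnegative",
               class = "reportlife_parameter_error")
  expect_error(relevance_score(1), "either", class = "reportlife_usage_error")
})

test_that("rank_reports orders by highlight, score, then recency", {
  t0 <- ts("2007-12-31 00:00:00")
  # same department: the newer report ranks first
  same <- data.table::data.table(
    report_id = c("Rold", "Rnew"), department = "clinical-pathology",
    available_at = c(t0 - 40 * 86400, t0 - 2 * 86400),
    age_days = c(40, 2))
  rk <- rank_reports(same, dept_medians = list(`clinical-pathology` = 15))
  expect_identical(rk$report_id, c("Rnew", "Rold"))

  # a young pathology report (median 118 d) outranks a haemostasis report
  # older than its 1-day median
  mixed <- data.table::data.table(
    report_id = c("Rpath", "Rhaem"),
    department = c("pathology", "haemostasis"),
    available_at = c(t0 - 30 * 86400, t0 - 3 * 86400),
    age_days = c(30, 3))
  rk2 <- rank_reports(mixed,
                      dept_medians = list(pathology = 118, haemostasis = 1))
  expect_identical(rk2$report_id, c("Rpath", "Rhaem"))
  expect_true(rk2[report_id == "Rpath", highlight])
  expect_false(rk2[report_id == "Rhaem", highlight])

  # random sets equal a brute-force comparator sort
  set.seed(13)
  n <- 60
  rnd <- data.table::data.table(
    report_id = sprintf("R%02d", 1:n),
    department = sample(c("a", "b", "c"), n, TRUE),
    available_at = t0 - runif(n, 0, 400) * 86400)
  rnd[, age_days := as.numeric(t0 - available_at, units = "days")]
  meds <- list(a = 5, b = 50, c = 200)
  rk3 <- rank_reports(rnd, dept_medians = meds)
  oracle <- data.table::copy(rnd)
  oracle[, highlight := age_days <= unlist(meds)[department]]
  oracle[, score := as.numeric(highlight)]
  oracle <- oracle[order(-highlight, -score, -as.numeric(available_at),
                         report_id)]
  expect_identical(rk3$report_id, oracle$report_id)

  expect_error(rank_reports(rnd, dept_medians = list(a = 5)),
               "no aging model", class = "reportlife_usage_error")
  expect_error(rank_reports(rnd), "exactly one",
               class = "reportlife_usage_error")
})

test_that("mixture generation + binning + fitting recovers all four windows", {
  # round-trip recovery at the four published parameter pairs
  params <- list(c(0.58, 0.12), c(0.63, 0.131), c(0.72, 0.11), c(0.60, 0.125))
  for (i in seq_along(params)) {
    a <- params[[i]][1]; b <- params[[i]][2]
    ages <- generate_view_ages(2e5, a, b, seed = 100 + i) * month_days
    s <- suppressMessages(bin_view_ages(ages, max_months = 44))
    f <- fit_exponential(s)
    expect_lt(abs(f$params[["a"]] / a - 1), 0.05)
    expect_lt(abs(f$params[["b"]] / b - 1), 0.05)
    expect_gt(f$r2, 0.99)
  }
})
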