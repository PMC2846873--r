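# Report-aging models: monthly age bins, exponential / logarithmic trend
# fits with goodness-of-fit, model comparison, and the recency-based
# relevance score and ranking built on them.

#' Bin view ages into a monthly survival series
#'
#' For `x = 1..max_months`, `y(x)` is the complementary cumulative fraction
#' of views whose report age is at least `x` months (one month =
#' `r DAYS_PER_MONTH` days). Views older than `max_months` months simply
#' remain in every bin (they are at least `x` months old for all `x`); a
#' message reports how many there were.
#'
#' @param ages_days view ages in days (alternatively a classified-view table
#'   with a `report_age_days` column).
#' @param max_months largest age bin (default 44).
#' @param window optional label for the series (e.g. the calendar month of
#'   the views).
#' @return an object of class `age_bin_series`: a `data.table` with `x`
#'   (months) and `y` (fraction in `[0, 1]`, non-increasing), with
#'   attributes `n_views` and `window`.
#' @export
bin_view_ages <- function(ages_days, max_months = 44L, window = NULL) {
  if (is.data.frame(ages_days)) {
    stopifnot_cols(ages_days, "report_age_days", "classified_views")
    ages_days <- ages_days[["report_age_days"]]
  }
  ages_days <- ages_days[!is.na(ages_days)]
  if (length(ages_days) == 0L) {
    rl_stop("cannot bin an empty window", "reportlife_empty_stratum")
  }
  if (any(ages_days < 0)) {
    rl_stop("negative report ages", "reportlife_integrity_error")
  }
  months <- ages_days / DAYS_PER_MONTH
  n_over <- sum(months >= max_months + 1)
  if (n_over > 0) {
    message(sprintf(
      "bin_view_ages: %d view(s) older than %d months accumulate in the last bin",
      n_over, max_months))
  }
  x <- seq_len(max_months)
  y <- vapply(x, function(m) mean(months >= m), numeric(1))
  out <- data.table::data.table(x = x, y = y)
  data.table::setattr(out, "class",
                      c("age_bin_series", class(data.table::data.table())))
  data.table::setattr(out, "n_views", length(ages_days))
  data.table::setattr(out, "window", window)
  out
}

.as_series <- function(series) {
  if (!is.data.frame(series) || !all(c("x", "y") %in% names(series))) {
    rl_stop("series must carry x and y columns (see bin_view_ages)",
            "reportlife_usage_error")
  }
  data.table::as.data.table(series)[, .(x, y)]
}

.new_fit <- function(family, params, r2, n_points) {
  structure(list(family = family, params = params, r2 = r2,
                 n_points = n_points), class = "aging_fit")
}

#' @export
print.aging_fit <- function(x, ...) {
  eq <- if (x$family == "exponential") {
    sprintf("y = %.4g * exp(-%.4g x)", x$params[["a"]], x$params[["b"]])
  } else {
    sprintf("y = -%.4g * ln(x) + %.4g", x$params[["c"]], x$params[["d"]])
  }
  cat(sprintf("Aging fit (%s): %s   R^2 = %.3f  (%d points)\n",
              x$family, eq, x$r2, x$n_points))
  invisible(x)
}

#' Fit the exponential aging model
#'
#' Fits `y = a * exp(-b * x)` to a monthly survival series by ordinary least
#' squares on `(x, log y)` -- slope `-b`, intercept `log a` -- the
#' "trend line" convention; R-squared is reported on the log scale.
#' Nonpositive `y` points cannot be log-transformed and are dropped with a
#' warning. `method = "nls"` instead minimises squared error on the original
#' scale (Gauss-Newton started from the log-linear solution).
#'
#' @param series an `age_bin_series` (or any table with `x`, `y`).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return an `aging_fit` with `params["a"]`, `params["b"]`, `r2`, `n_points`.
#' @export
fit_exponential <- function(series, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  s <- .as_series(series)
  bad <- s$y <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d nonpositive y point(s) before log transform",
                    sum(bad)), call. = FALSE)
    s <- s[!bad]
  }
  if (nrow(s) < 3L) {
    rl_stop("need at least 3 positive points to fit the exponential model",
            "reportlife_parameter_error")
  }
  fit <- stats::lm(log(y) ~ x, data = s)
  a <- exp(unname(stats::coef(fit)[1L]))
  b <- -unname(stats::coef(fit)[2L])
  ly <- log(s$y)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  if (method == "nls") {
    # zero-residual (exact) data defeats Gauss-Newton; keep the log-linear
    # solution, which is already the least-squares optimum there
    nfit <- tryCatch(
      stats::nls(y ~ a * exp(-b * x), data = s, start = list(a = a, b = b)),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      a <- unname(stats::coef(nfit)[["a"]])
      b <- unname(stats::coef(nfit)[["b"]])
    }
    resid <- s$y - a * exp(-b * s$x)
    r2 <- 1 - sum(resid^2) / sum((s$y - mean(s$y))^2)
  }
  .new_fit("exponential", c(a = a, b = b), r2, nrow(s))
}

#' Fit the logarithmic aging model
#'
#' Fits `y = -c * log(x) + d` by ordinary least squares of `y` on `log(x)`;
#' R-squared on the original scale. Defined only for `x >= 1`.
#'
#' @param series an `age_bin_series` (or any table with `x`, `y`).
#' @return an `aging_fit` with `params["c"]`, `params["d"]`.
#' @export
fit_logarithmic <- function(series) {
  s <- .as_series(series)
  if (any(s$x < 1)) {
    rl_stop("logarithmic model is defined only for x >= 1",
            "reportlife_parameter_error")
  }
  if (nrow(s) < 3L) {
    rl_stop("need at least 3 points to fit the logarithmic model",
            "reportlife_parameter_error")
  }
  fit <- stats::lm(y ~ log(x), data = s)
  d <- unname(stats::coef(fit)[1L])
  cc <- -unname(stats::coef(fit)[2L])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((s$y - mean(s$y))^2)
  .new_fit("logarithmic", c(c = cc, d = d), r2, nrow(s))
}

#' Compare aging-model families across fitting windows
#'
#' @param fits list of `aging_fit` objects (both families, fitted on the
#'   same windows).
#' @param r2_threshold threshold for the high-goodness-of-fit count.
#' @return a list with per-family `mean_r2` and `n_r2_above`, and `winner`
#'   (family with the higher mean R-squared, or `"tie"`).
#' @export
compare_models <- function(fits, r2_threshold = 0.9) {
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "aging_fit"))) {
    rl_stop("fits must be a nonempty list of aging_fit objects",
            "reportlife_usage_error")
  }
  fam <- vapply(fits, `[[`, character(1), "family")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  by_fam <- lapply(split(r2, fam), function(v) {
    list(mean_r2 = mean(v), n_r2_above = sum(v > r2_threshold),
         n_windows = length(v))
  })
  means <- vapply(by_fam, `[[`, numeric(1), "mean_r2")
  winner <- if (length(means) > 1L && abs(diff(range(means))) < 1e-12) {
    "tie"
  } else {
    names(means)[which.max(means)]
  }
  list(families = by_fam, winner = winner)
}

#' Recency-based relevance score for a report
#'
#' Converts report age into an estimated relevance. In model mode the score
#' is the fitted survival fraction `a * exp(-b * age_months)` clipped to
#' `[0, 1]` -- the estimated share of this report class's views still to
#' come -- and a report is highlighted while its age is below the model's
#' implied median life (`log(2 a)/b` months when `a > 0.5`, else 0). In
#' threshold mode the report is highlighted exactly when its age does not
#' exceed the stratum's empirical median life, and the score is the
#' indicator.
#'
#' @param age_days report age(s) in days (nonnegative).
#' @param fit an `aging_fit` of the exponential family (model mode).
#' @param median_life_days stratum median life in days (threshold mode).
#' @return a `data.table` with `score` in `[0, 1]` and `highlight`.
#' @export
relevance_score <- function(age_days, fit = NULL, median_life_days = NULL) {
  if (any(age_days < 0, na.rm = TRUE)) {
    rl_stop("age_days must be nonnegative", "reportlife_parameter_error")
  }
  if (!is.null(fit)) {
    if (!inherits(fit, "aging_fit") || fit$family != "exponential") {
      rl_stop("model mode needs an exponential aging_fit",
              "reportlife_usage_error")
    }
    a <- fit$params[["a"]]; b <- fit$params[["b"]]
    months <- age_days / DAYS_PER_MONTH
    score <- pmin(pmax(a * exp(-b * months), 0), 1)
    half_life <- if (a > 0.5) log(2 * a) / b else 0
    data.table::data.table(score = score, highlight = months <= half_life)
  } else if (!is.null(median_life_days)) {
    highlight <- age_days <= median_life_days
    data.table::data.table(score = as.numeric(highlight),
                           highlight = highlight)
  } else {
    rl_stop("provide either fit or median_life_days", "reportlife_usage_error")
  }
}

#' Rank reports by estimated relevance
#'
#' Scores each report against its department's aging model or empirical
#' median life and orders the list by highlight status, then score, then
#' recency (stable sort, deterministic given inputs).
#'
#' @param reports table with `report_id`, `department`, `available_at` and
#'   `age_days` (age at ranking time).
#' @param dept_fits named list mapping department to an exponential
#'   `aging_fit` (model mode) ...
#' @param dept_medians ... or to a median life in days (threshold mode).
#'   Exactly one of the two must be given; every department present in
#'   `reports` must be resolvable.
#' @return the reports table with `score`, `highlight` and `rank` columns,
#'   ordered by rank.
#' @export
rank_reports <- function(reports, dept_fits = NULL, dept_medians = NULL) {
  re <- data.table::as.data.table(reports)
  stopifnot_cols(re, c("report_id", "department", "available_at", "age_days"),
                 "reports")
  if (is.null(dept_fits) == is.null(dept_medians)) {
    rl_stop("provide exactly one of dept_fits or dept_medians",
            "reportlife_usage_error")
  }
  lookup <- dept_fits %||% dept_medians
  missing <- setdiff(unique(re$department), names(lookup))
  if (length(missing)) {
    rl_stop(sprintf("no aging model / median life for department(s): %s",
                    paste(missing, collapse = ", ")),
            "reportlife_usage_error")
  }
  re <- data.table::copy(re)
  scored <- lapply(seq_len(nrow(re)), function(i) {
    if (!is.null(dept_fits)) {
      relevance_score(re$age_days[i], fit = lookup[[re$department[i]]])
    } else {
      relevance_score(re$age_days[i],
                      median_life_days = lookup[[re$department[i]]])
    }
  })
  re[, score := vapply(scored, `[[`, numeric(1), "score")]
  re[, highlight := vapply(scored, `[[`, logical(1), "highlight")]
  re[, available_at := as_utc(available_at)]
  data.table::setorder(re, -highlight, -score, -available_at, report_id)
  re[, rank := .I]
  re[]
}
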