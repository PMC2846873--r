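# Shared helpers: error signalling, seed derivation, time arithmetic.

# One "month" of report age, in days. Monthly age bins are defined on this
# grid; the Gregorian average keeps month->day conversion exact and symmetric.
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed reportlife error
#'
#' All user-facing failures in the package raise conditions of class
#' `reportlife_error` plus a specific subclass (`reportlife_parameter_error`,
#' `reportlife_config_error`, `reportlife_integrity_error`,
#' `reportlife_schema_error`, `reportlife_usage_error`,
#' `reportlife_empty_stratum`), so callers can route on failure kind.
#'
#' @param msg message text.
#' @param class specific condition subclass.
#' @param call. logical; include the call.
#' @keywords internal
rl_stop <- function(msg, class = "reportlife_error", call. = FALSE) {
  stop(structure(
    class = c(class, "reportlife_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

# Validate a probability-mix vector (named, nonnegative, sums to 1 +- 1e-9).
check_mix <- function(mix, what) {
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    rl_stop(sprintf("%s must be a named numeric vector", what),
            "reportlife_parameter_error")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    rl_stop(sprintf("%s must be nonnegative and sum to 1 (got sum %.12g)",
                    what, sum(mix)),
            "reportlife_parameter_error")
  }
  invisible(mix)
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Deterministic 31-bit hash used to split the random-number stream per table
#' and per draw, so that independently keyed draws do not interact and
#' enlarging one table leaves previously generated rows unchanged.
#'
#' @param seed master integer seed.
#' @param key character key naming the stream.
#' @return an integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG.
with_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}

# POSIXct (UTC) from ISO-8601-ish strings; all package timestamps are UTC.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

# Difference in fractional days.
diff_days <- function(later, earlier) {
  as.numeric(difftime(as_utc(later), as_utc(earlier), units = "days"))
}

# Calendar quarter label "YYYYQn" for a timestamp vector.
quarter_label <- function(t) {
  t <- as_utc(t)
  y <- as.integer(format(t, "%Y"))
  q <- (as.integer(format(t, "%m")) - 1L) %/% 3L + 1L
  sprintf("%dQ%d", y, q)
}

# Calendar date (Date, UTC) of a timestamp.
utc_date <- function(t) as.Date(as_utc(t), tz = "UTC")

stopifnot_cols <- function(dt, cols, table) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    rl_stop(sprintf("table '%s' is missing required column(s): %s",
                    table, paste(missing, collapse = ", ")),
            "reportlife_schema_error")
  }
  invisible(dt)
}
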