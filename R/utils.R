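# shared internal helpers: dates, ages, RNG hygiene, small checks

# Middle month of a quarter is month 3q-1 (Feb, May, Aug, Nov); day 15 is
# the deterministic mid-quarter imputation used everywhere birth dates are
# needed, since records carry only year + quarter of birth.
mid_quarter_date <- function(birth_year, birth_quarter) {
  stopifnot(all(birth_quarter %in% 1:4))
  as.Date(sprintf("%04d-%02d-15", as.integer(birth_year),
                  3L * as.integer(birth_quarter) - 1L))
}

# Completed years between birth and date; may be negative (callers decide
# whether that is an error).  Vectorised, recycles.
age_completed_years <- function(date, birth) {
  d <- as.POSIXlt(date)
  b <- as.POSIXlt(birth)
  anniversary_pending <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  (d$year - b$year) - as.integer(anniversary_pending)
}

#' Age in completed years from a quarter-coarsened birth date
#'
#' Records carry only the year and quarter of birth, so ages are computed
#' from a deterministic mid-quarter imputed birth date: day 15 of the
#' quarter's middle month (Q1 -> Feb 15, Q2 -> May 15, Q3 -> Aug 15,
#' Q4 -> Nov 15).
#'
#' @param date `Date` (or coercible) reference date(s).
#' @param birth_year,birth_quarter Integer year and quarter (1-4) of birth.
#' @return Integer vector of ages in completed years.
#' @examples
#' age_on(as.Date("2005-01-01"), 2000, 1)  # 4
#' age_on(as.Date("2019-01-01"), 2000, 4)  # 18
#' @export
age_on <- function(date, birth_year, birth_quarter) {
  date <- as.Date(date)
  birth <- mid_quarter_date(birth_year, birth_quarter)
  age <- age_completed_years(date, birth)
  if (any(age < 0, na.rm = TRUE)) {
    abort("`date` precedes the imputed birth date: negative age.")
  }
  age
}

year_of <- function(date) as.integer(format(as.Date(date), "%Y"))

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

check_probability <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("configuration error: `%s` must be a probability in [0, 1].",
                  field))
  }
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("configuration error: `%s` must be a non-negative integer.",
                  field))
  }
  invisible(as.integer(x))
}

# ATC codes are hierarchical: letter, two digits, then optional
# letter / letter / two-digit levels (e.g. R03, R01AC, R06AE07).
atc_pattern <- "^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$"

is_valid_atc <- function(x) grepl(atc_pattern, x)
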