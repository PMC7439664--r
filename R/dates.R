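#' Calendar-month date arithmetic
#'
#' All window semantics in the engine ("within 6 months", "expire after 9
#' months") are defined in calendar months, not fixed-length days. These two
#' helpers are the single implementation used engine-wide so the lab-window
#' and pregnancy-expiry boundaries stay consistent.
#'
#' `add_months()` shifts a date by whole calendar months, clamping the
#' day-of-month to the target month's length (2020-01-31 plus one month is
#' 2020-02-29, not a rollover into March).
#'
#' @param date a `Date` (or string coercible via [as_date()]).
#' @param n integer number of months; may be negative.
#' @return `add_months()`: a `Date`.
#' @examples
#' add_months(as.Date("2020-01-31"), 1)   # 2020-02-29
#' add_months(as.Date("2020-03-15"), -6)  # 2019-09-15
#' @export
add_months <- function(date, n) {
  date <- as_date(date)
  stopifnot(length(n) == 1L, n == as.integer(n))
  lt <- as.POSIXlt(date)
  mon0 <- lt$year * 12L + lt$mon + as.integer(n)
  year <- mon0 %/% 12L + 1900L
  mon <- mon0 %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(year, mon))
  as.Date(sprintf("%04d-%02d-%02d", year, mon, day))
}

days_in_month <- function(year, mon) {
  lens <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(mon == 2L & leap, 29L, lens[mon])
}

#' @describeIn add_months is `date` inside the half-open lookback window
#'   `(as_of - window_months, as_of]`? A result exactly `window_months`
#'   calendar months old is excluded (conservative freshness).
#' @param as_of evaluation instant (`Date`).
#' @param window_months positive integer width of the lookback window.
#' @export
within_window <- function(date, as_of, window_months) {
  date <- as_date(date)
  as_of <- as_date(as_of)
  lower <- add_months(as_of, -window_months)
  date > lower & date <= as_of
}

#' Coerce to Date, strictly
#'
#' ISO-8601 `YYYY-MM-DD` strings and `Date`s are accepted; anything else
#' (including `NA`) is an error. Used by every constructor that takes a date
#' so malformed input fails loudly at ingestion, not mid-evaluation.
#'
#' @param x a `Date` or ISO-8601 date string.
#' @return a `Date` of the same length.
#' @export
as_date <- function(x) {
  if (!inherits(x, "Date") && !is.character(x) && anyNA(x))
    stop("NA date", call. = FALSE)
  if (inherits(x, "Date")) {
    if (anyNA(x)) stop("NA date", call. = FALSE)
    return(x)
  }
  if (is.character(x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(d)) stop("not an ISO-8601 date: ", paste(x[is.na(d)], collapse = ", "),
                       call. = FALSE)
    return(d)
  }
  stop("expected a Date or ISO-8601 string, got ", class(x)[1], call. = FALSE)
}

#' Age in completed years at a reference date
#'
#' Age is always computed against an explicit as-of date, never the wall
#' clock, so evaluations are reproducible.
#'
#' @param birth_date,as_of `Date`s.
#' @return integer age in completed years.
#' @export
age_at <- function(birth_date, as_of) {
  birth_date <- as_date(birth_date)
  as_of <- as_date(as_of)
  bd <- as.POSIXlt(birth_date); ref <- as.POSIXlt(as_of)
  age <- ref$year - bd$year
  before_birthday <- ref$mon < bd$mon | (ref$mon == bd$mon & ref$mday < bd$mday)
  as.integer(age - ifelse(before_birthday, 1L, 0L))
}
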