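# Shared helpers: calendar arithmetic, rounding, condition constructors.

#' Add calendar months to a date, clamping to month end
#'
#' Interval conventions such as "within 6 months" or ">= 3 months apart" are
#' evaluated with calendar-month arithmetic: the same day-of-month `n` months
#' later, clamped to the last day of the target month (2018-01-31 plus one
#' month is 2018-02-28), boundaries inclusive.
#'
#' @param date a `Date` vector
#' @param n integer number of months (may be negative; recycled against
#'   `date`)
#' @return a `Date` vector
#' @export
#' @examples
#' add_months(as.Date("2018-01-31"), 1)  # 2018-02-28
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"), all(is.finite(n)))
  if (length(date) && length(n) > length(date)) date <- rep_len(date, length(n))
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- rep_len(1L, length(day))
  lt$mon <- lt$mon + as.integer(rep_len(n, length(day)))
  first <- as.Date(lt)
  # days in target month
  nxt <- as.POSIXlt(first)
  nxt$mon <- nxt$mon + 1L
  ndays <- as.integer(as.Date(nxt) - first)
  first + pmin(day, ndays) - 1L
}

#' Round half away from zero
#'
#' Report percentages use commercial (half-up) rounding, not the IEEE
#' round-half-even of [base::round()], so that recomputed table cells match
#' conventionally rounded published values digit for digit.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Age in completed years at a reference date
#'
#' @param birth_date,ref_date `Date` vectors (recycled)
#' @return integer vector of completed years
#' @export
age_at <- function(birth_date, ref_date) {
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(ref_date)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(age - before_birthday)
}

# classed error helpers ------------------------------------------------------

cf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "carefrag_error"), call = call))
}

cf_validation_stop <- function(msg, subclass) {
  cf_stop(msg, class = c(subclass, "carefrag_validation_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_strict <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- is.na(x) | x == ""
  out[!ok] <- as.Date(x[!ok], format = "%Y-%m-%d")
  bad <- which(!ok & is.na(out))
  if (length(bad)) {
    cf_validation_stop(
      sprintf("%s: unparseable ISO-8601 date at row(s) %s (e.g. \"%s\")",
              what, paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]),
      "carefrag_date_error")
  }
  out
}
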