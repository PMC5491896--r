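#' Parse ISO-8601 dates strictly
#'
#' Accepts only `YYYY-MM-DD` strings that name a real calendar day.
#' Anything else (including partial dates, slashes, or impossible days
#' such as `2015-02-30`) parses to `NA`.
#'
#' @param x Character vector of candidate dates.
#' @return A `Date` vector; unparsable or missing entries are `NA`.
#' @export
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # as.Date rolls over impossible days on some platforms; verify round-trip
    d[!is.na(d) & format(d, "%Y-%m-%d") != x[ok]] <- NA
    out[ok] <- d
  }
  out
}

#' Age in whole years at a reference date
#'
#' Floor of complete years between birth date and `ref_date`.  Missing or
#' unparsable birth dates propagate to `NA` rather than raising an error,
#' matching the engine's missing-data semantics (an age predicate over an
#' unknown age is simply false).
#'
#' @param birth_date Character (`YYYY-MM-DD`) or `Date` vector.
#' @param ref_date Reference date (scalar or vector, recycled).
#' @return Integer vector of ages; `NA` where birth date is missing/invalid
#'   or later than `ref_date`.
#' @examples
#' age_at("1950-06-01", as.Date("2015-06-01"))  # 65: exact anniversary
#' age_at("1950-06-02", as.Date("2015-06-01"))  # 64: day before anniversary
#' @export
age_at <- function(birth_date, ref_date) {
  bd <- parse_iso_date(birth_date)
  rd <- parse_iso_date(ref_date)
  n <- max(length(bd), length(rd))
  bd <- rep_len(bd, n)
  rd <- rep_len(rd, n)
  b <- as.POSIXlt(bd)
  r <- as.POSIXlt(rd)
  yrs <- r$year - b$year
  before <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  yrs <- yrs - as.integer(before)
  yrs[is.na(bd) | is.na(rd)] <- NA_integer_
  yrs[!is.na(yrs) & yrs < 0] <- NA_integer_
  as.integer(yrs)
}

#' First day of a "past N months" lookback window
#'
#' The probes speak of "the past 24 months" and "the past 12 months";
#' month arithmetic is pinned to a fixed-day convention so that windows
#' are reproducible: N months = `floor(N * 365.25 / 12)` days, and the
#' lookback interval is closed on both ends.
#'
#' @param ref_date Reference date.
#' @param months Number of months to look back.
#' @return A `Date`: the earliest day inside the lookback window.
#' @export
months_before <- function(ref_date, months) {
  rd <- parse_iso_date(ref_date)
  rd - floor(months * 365.25 / 12)
}
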