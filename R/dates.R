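# Calendar arithmetic.  A "year" is 365.25 days throughout, so risk windows
# are leap-year stable; dates are base `Date` (integer days).

DAYS_PER_YEAR <- 365.25

#' Add a (possibly fractional) number of years to a date
#' @param date a `Date`
#' @param years numeric, years to add (365.25-day years)
#' @return a `Date`
#' @export
add_years <- function(date, years) {
  as.Date(date) + round(years * DAYS_PER_YEAR)
}

#' Elapsed time between two dates in 365.25-day years
#' @param from,to `Date`s
#' @return numeric years
#' @export
years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR
}

#' Completed years of age at an event
#' @param birth_date,at `Date`s
#' @return integer, floor of the elapsed years
#' @export
age_at <- function(birth_date, at) {
  as.integer(floor(years_between(birth_date, at)))
}
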