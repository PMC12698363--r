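#' Day-of-year on a fixed 1-365 grid
#'
#' Maps calendar dates to a day-of-year index on a 365-day cycle. In leap
#' years February 29 is mapped to day 59, i.e. it shares the index of
#' February 28, and all later days keep the index they have in common years.
#' This keeps the cyclic seasonal basis on a fixed 1-365 grid with period
#' exactly 365 while retaining leap-day rows in the analysis panel.
#'
#' @param date a `Date` vector.
#' @return integer vector in 1..365.
#' @export
doy365 <- function(date) {
  date <- as.Date(date)
  yd <- as.integer(format(date, "%j"))
  leap <- is_leap_year(as.integer(format(date, "%Y")))
  ifelse(leap & yd >= 60L, yd - 1L, yd)
}

#' @rdname doy365
#' @param year integer vector of years.
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Count region-days in an inclusive date range
#'
#' The number of calendar days from `start_date` to `end_date` inclusive,
#' multiplied by the number of regions. For 1995-01-01 to 2020-12-31 and 47
#' regions this is 446,359 region-days.
#'
#' @param start_date,end_date `Date` (or coercible) bounds, inclusive.
#' @param n_regions number of regions.
#' @return integer count.
#' @export
count_prefecture_days <- function(start_date, end_date, n_regions) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) stop("start_date must be <= end_date")
  n_days <- as.integer(end_date - start_date) + 1L
  n_days * as.integer(n_regions)
}

#' Build calendar covariates for a date vector
#'
#' Given dates and a holiday calendar, computes the covariates used by the
#' regression models: `doy` (1-365, leap-day rule of [doy365()]), `dow`
#' (Monday = 1 .. Sunday = 7), `year`, and indicator columns for holidays and
#' the named special days. New Year's Eve (Dec 31) is not a statutory holiday
#' and is flagged separately; it sets `is_holiday` only if it appears as an
#' ordinary labelled row in the calendar. New Year's Day and Coming-of-Age
#' Day set both their own flag and `is_holiday`.
#'
#' @param date a `Date` vector.
#' @param holidays a holiday calendar data frame with columns `date` and
#'   `label`, as from [read_holidays()] or [make_holiday_calendar()]. Labels
#'   `"new_years_day"`, `"new_years_eve"` and `"coming_of_age_day"` are
#'   recognised specially.
#' @return a data frame of calendar covariates, one row per input date.
#' @export
calendar_covariates <- function(date, holidays = NULL) {
  date <- as.Date(date)
  out <- data.frame(
    date = date,
    year = as.integer(format(date, "%Y")),
    doy = doy365(date),
    # %u: ISO weekday, Monday = 1
    dow = as.integer(format(date, "%u")),
    is_holiday = FALSE,
    is_new_years_day = FALSE,
    is_new_years_eve = FALSE,
    is_coming_of_age_day = FALSE
  )
  if (!is.null(holidays) && nrow(holidays) > 0) {
    holidays <- validate_holidays(holidays)
    idx <- match(date, holidays$date)
    hit <- !is.na(idx)
    lab <- holidays$label[idx[hit]]
    out$is_new_years_day[hit] <- lab == "new_years_day"
    out$is_new_years_eve[hit] <- lab == "new_years_eve"
    out$is_coming_of_age_day[hit] <- lab == "coming_of_age_day"
    out$is_holiday[hit] <- lab != "new_years_eve"
  }
  out
}

validate_holidays <- function(holidays) {
  stopifnot(all(c("date", "label") %in% names(holidays)))
  holidays$date <- as.Date(holidays$date)
  if (anyDuplicated(holidays$date))
    stop("duplicate dates in holiday calendar")
  holidays
}

second_monday_of_january <- function(year) {
  d <- as.Date(sprintf("%d-01-01", year)) + 0:13
  d[format(d, "%u") == "1"][2]
}

#' Generate a synthetic national-holiday calendar
#'
#' Builds a Japanese-style statutory holiday calendar for use with the
#' synthetic-data generator: New Year's Day (Jan 1), Coming-of-Age Day
#' (Jan 15 through 1999, the second Monday of January from 2000, following
#' the statute change), a set of fixed-date holidays through the year, and a
#' New Year's Eve row (Dec 31, labelled `"new_years_eve"`, which is not a
#' statutory holiday and is only flagged separately downstream). This is a
#' synthetic approximation of the statutory calendar -- it omits
#' substitute-holiday rules and movable equinox dates -- sufficient for the
#' generator's ground-truth day-type effects.
#'
#' @param years integer vector of years to cover.
#' @return data frame with columns `date`, `label`.
#' @export
make_holiday_calendar <- function(years) {
  years <- sort(unique(as.integer(years)))
  fixed <- c(
    "02-11" = "national_foundation_day",
    "04-29" = "spring_holiday",
    "05-03" = "constitution_day",
    "05-04" = "greenery_day",
    "05-05" = "childrens_day",
    "07-20" = "marine_day",
    "09-15" = "respect_for_aged_day",
    "10-10" = "sports_day",
    "11-03" = "culture_day",
    "11-23" = "labour_thanksgiving_day",
    "12-23" = "winter_holiday"
  )
  rows <- lapply(years, function(y) {
    coa <- if (y <= 1999) as.Date(sprintf("%d-01-15", y)) else
      second_monday_of_january(y)
    data.frame(
      date = c(as.Date(sprintf("%d-01-01", y)), coa,
               as.Date(sprintf("%d-%s", y, names(fixed))),
               as.Date(sprintf("%d-12-31", y))),
      label = c("new_years_day", "coming_of_age_day", unname(fixed),
                "new_years_eve")
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$date), , drop = FALSE]
}
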