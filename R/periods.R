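#' Analysis periods around the 2020 German casino closures
#'
#' The analysis compares posting behaviour in four whole-week windows: the two
#' nationwide lockdowns during which German gambling venues were closed, and
#' the seven weeks immediately preceding each. Lockdown 1 runs from Monday
#' 2020-03-16 to Sunday 2020-05-03; lockdown 2 from Monday 2020-11-02 to
#' Sunday 2020-12-20 (chosen to match the length of lockdown 1). Each
#' pre-lockdown window is the 49 days ending the day before its lockdown.
#'
#' @return A data frame with one row per period and columns `period`
#'   (character: `"pre_lockdown_1"`, `"lockdown_1"`, `"pre_lockdown_2"`,
#'   `"lockdown_2"`), `start` and `end` (`Date`, both inclusive).
#' @examples
#' default_periods()
#' @export
default_periods <- function() {
  p <- data.frame(
    period = c("pre_lockdown_1", "lockdown_1", "pre_lockdown_2", "lockdown_2"),
    start  = as.Date(c("2020-01-27", "2020-03-16", "2020-09-14", "2020-11-02")),
    end    = as.Date(c("2020-03-15", "2020-05-03", "2020-11-01", "2020-12-20")),
    stringsAsFactors = FALSE
  )
  validate_periods(p)
  p
}

period_names <- function() {
  c("pre_lockdown_1", "lockdown_1", "pre_lockdown_2", "lockdown_2")
}

validate_periods <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("period", "start", "end") %in% names(periods)))
  if (any(periods$end < periods$start))
    stop("period end date precedes start date", call. = FALSE)
  # whole weeks, Monday through Sunday
  wd <- function(d) as.POSIXlt(d)$wday
  if (any(wd(periods$start) != 1L))
    stop("period start dates must be Mondays", call. = FALSE)
  if (any(wd(periods$end) != 0L))
    stop("period end dates must be Sundays", call. = FALSE)
  # pairwise disjoint
  n <- nrow(periods)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (periods$start[i] <= periods$end[j] && periods$start[j] <= periods$end[i])
        stop(sprintf("periods '%s' and '%s' overlap",
                     periods$period[i], periods$period[j]), call. = FALSE)
    }
  }
  invisible(periods)
}

#' Civil date of a timestamp
#'
#' Timestamps are stored in UTC; period membership and weekly series are
#' decided on the civil date in the Europe/Berlin timezone, because the venue
#' closures that define the periods are German calendar events.
#'
#' @param x a `POSIXct` vector, or a `Date` (returned unchanged).
#' @return a `Date` vector.
#' @keywords internal
civil_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, tz = "Europe/Berlin")
}

#' Assign timestamps to analysis periods
#'
#' @param x timestamps (`POSIXct`, interpreted via their timezone and
#'   converted to Europe/Berlin civil dates) or `Date`s.
#' @param periods a period table as returned by [default_periods()].
#' @return character vector: the period name containing each timestamp, or
#'   `NA` for timestamps outside every period.
#' @examples
#' assign_period(as.Date(c("2020-03-16", "2020-05-04")))
#' @export
assign_period <- function(x, periods = default_periods()) {
  d <- civil_date(x)
  out <- rep(NA_character_, length(d))
  for (i in seq_len(nrow(periods))) {
    hit <- !is.na(d) & d >= periods$start[i] & d <= periods$end[i]
    out[hit] <- periods$period[i]
  }
  out
}

#' ISO-8601 calendar week of a date
#'
#' Weeks run Monday to Sunday; week 1 is the week containing January 4th
#' (ISO 8601). Dates near New Year may therefore belong to a week of the
#' neighbouring ISO year, e.g. 2021-01-01 falls in week 53 of ISO year 2020.
#'
#' @param x a `Date` vector (or `POSIXct`, reduced to its Berlin civil date).
#' @return a data frame with integer columns `year` (ISO week-based year) and
#'   `week` (1--53).
#' @examples
#' calendar_week(as.Date(c("2020-03-16", "2021-01-01")))
#' @export
calendar_week <- function(x) {
  d <- civil_date(x)
  data.frame(year = as.integer(format(d, "%G")),
             week = as.integer(format(d, "%V")))
}

#' First day (Monday) of an ISO calendar week
#' @keywords internal
iso_week_start <- function(year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  week1_monday <- jan4 - (as.POSIXlt(jan4)$wday - 1L) %% 7L
  week1_monday + 7L * (week - 1L)
}
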