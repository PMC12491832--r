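#' Bat-day and bat-year calendar conventions
#'
#' Hibernation phenology at a hibernaculum is naturally organised around two
#' calendar conventions. A \emph{bat day} runs from noon to noon, so that a
#' single night of activity falls on one date: timestamps at or after 12:00
#' belong to that calendar date's bat day, timestamps before 12:00 to the
#' previous date's. A \emph{bat year} runs from 1 July to 30 June of the
#' following calendar year, so that one winter is never split across analysis
#' years; it is labelled by the calendar year containing its 1 July.
#'
#' @param timestamp a \code{POSIXct} vector (timezone-naive local time).
#' @return \code{bat_day}: a \code{Date} vector, the date of the noon opening
#'   the bat day each timestamp falls in.
#' @examples
#' bat_day(as.POSIXct("2015-11-03 13:00:00", tz = "UTC"))  # 2015-11-03
#' bat_day(as.POSIXct("2015-11-03 11:59:00", tz = "UTC"))  # 2015-11-02
#' bat_year(as.Date("2016-06-30"))  # 2015
#' @export
bat_day <- function(timestamp) {
  stopifnot(inherits(timestamp, "POSIXct"))
  lt <- as.POSIXlt(timestamp)
  d <- as.Date(format(timestamp, "%Y-%m-%d"))
  # noon boundary is inclusive at 12:00:00: [12:00, next 12:00)
  before_noon <- lt$hour < 12
  d[before_noon] <- d[before_noon] - 1L
  d
}

#' @param date a \code{Date} vector (typically a bat day).
#' @return \code{bat_year}: an integer vector, the bat-year label (the
#'   calendar year containing the bat year's 1 July).
#' @rdname bat_day
#' @export
bat_year <- function(date) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  yr <- lt$year + 1900L
  ifelse(lt$mon + 1L >= 7L, yr, yr - 1L)
}

#' First day (1 July) of a bat year
#' @param year integer bat-year label(s).
#' @return Date vector of the 1 July opening each bat year.
#' @keywords internal
bat_year_origin <- function(year) {
  as.Date(paste0(year, "-07-01"))
}

#' Day index within a bat year
#'
#' Days elapsed since 1 July of the given bat year, the response encoding
#' used by the trend models (1 July = 0). Hibernation start indices typically
#' run 60--215, end indices 183--304.
#'
#' @param date Date vector.
#' @param year integer bat-year label(s), recycled against \code{date}.
#' @return integer day counts.
#' @export
day_index <- function(date, year = bat_year(date)) {
  as.integer(date - bat_year_origin(year))
}

# Eligibility windows of the longest-hibernation-period definition, as Dates
# for bat year Y: start in [1 Jul Y, 1 Feb Y+1], end in [31 Dec Y, 30 Apr Y+1].
# Both bounds inclusive.
hib_windows <- function(year) {
  list(
    start_lo = as.Date(paste0(year, "-07-01")),
    start_hi = as.Date(paste0(year + 1L, "-02-01")),
    end_lo   = as.Date(paste0(year, "-12-31")),
    end_hi   = as.Date(paste0(year + 1L, "-04-30"))
  )
}
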