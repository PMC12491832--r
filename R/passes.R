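#' Build directed gate passes from raw reader hits
#'
#' Reconstructs crossings of the hibernaculum entrance from individual
#' antenna hits. Within one tag, entrance and reader, hits closer together
#' than \code{burst_window} seconds (re-triggering during a slow crawl) are
#' first collapsed to the earliest hit of the burst. Then, within one tag and
#' entrance, an inner and an outer hit within \code{pairing_window} seconds
#' are paired greedily left-to-right in time into one pass: outer-then-inner
#' is an \code{entry}, inner-then-outer an \code{exit}. Hits that cannot be
#' paired, and all \code{"only"}-reader hits from single-reader data, become
#' passes with direction \code{unknown}. Every hit is consumed by exactly
#' one pass.
#'
#' @param events detection events as from [read_detections()] (sorted by
#'   tag_id then timestamp).
#' @param pairing_window maximum seconds between the two hits of one
#'   crossing; default 60 (a 20 cm crawl between readers takes seconds).
#' @param burst_window seconds within which same-reader re-triggers are
#'   collapsed; default 5.
#' @return data frame of passes: \code{tag_id}, \code{timestamp} (first hit
#'   of the pair), \code{entrance_id}, \code{direction} (\code{entry},
#'   \code{exit} or \code{unknown}), \code{bat_day}, \code{bat_year}.
#' @export
build_passes <- function(events, pairing_window = 60, burst_window = 5) {
  if (pairing_window < 0 || burst_window < 0) {
    stop("pairing_window and burst_window must be non-negative",
         call. = FALSE)
  }
  empty <- data.frame(tag_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      entrance_id = integer(), direction = character(),
                      bat_day = as.Date(character()), bat_year = integer())
  if (is.null(events) || nrow(events) == 0) return(empty)

  ev <- events[order(events$tag_id, events$entrance_id, events$reader,
                     events$timestamp), , drop = FALSE]
  # burst collapse: new burst when the gap to the previous same-group hit
  # exceeds burst_window
  t <- as.numeric(ev$timestamp)
  grp <- paste(ev$tag_id, ev$entrance_id, ev$reader, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap <- c(Inf, diff(t))
  keep <- new_grp | gap > burst_window
  ev <- ev[keep, , drop = FALSE]

  ev <- ev[order(ev$tag_id, ev$entrance_id, ev$timestamp, ev$reader), ,
           drop = FALSE]
  n <- nrow(ev)
  t <- as.numeric(ev$timestamp)
  same <- ev$tag_id == c(ev$tag_id[-1], NA) &
    ev$entrance_id == c(ev$entrance_id[-1], NA)
  dual <- ev$reader %in% c("inner", "outer")
  opposite <- dual & c(dual[-1], FALSE) &
    ev$reader != c(ev$reader[-1], NA)
  pairable <- !is.na(same) & same & opposite &
    (c(t[-1], NA) - t) <= pairing_window

  direction <- character(n)
  first_of_pair <- logical(n)
  i <- 1L
  while (i <= n) {
    if (i < n && pairable[i]) {
      first_of_pair[i] <- TRUE
      direction[i] <- if (ev$reader[i] == "outer") "entry" else "exit"
      direction[i + 1L] <- ""  # consumed as second hit
      i <- i + 2L
    } else {
      first_of_pair[i] <- TRUE
      direction[i] <- "unknown"
      i <- i + 1L
    }
  }
  p <- ev[first_of_pair, , drop = FALSE]
  p$direction <- direction[first_of_pair]
  p$bat_day <- bat_day(p$timestamp)
  p$bat_year <- bat_year(p$bat_day)
  out <- p[, c("tag_id", "timestamp", "entrance_id", "direction",
               "bat_day", "bat_year")]
  out <- out[order(out$tag_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effective age class in a given bat year
#'
#' Bats tagged as juveniles are juveniles only in the bat year of tagging
#' and are considered adults after their first year; bats tagged as adults
#' are always adults.
#'
#' @param age_at_tagging \code{"juvenile"} or \code{"adult"} (vectorised).
#' @param tagging_date capture date (Date).
#' @param year bat-year label(s) being asked about.
#' @return character vector, \code{"juvenile"} or \code{"adult"}.
#' @export
effective_age <- function(age_at_tagging, tagging_date, year) {
  tag_by <- bat_year(as.Date(tagging_date))
  if (any(year < tag_by)) {
    stop("bat_year precedes the tagging bat year", call. = FALSE)
  }
  ifelse(age_at_tagging == "juvenile" & year == tag_by, "juvenile", "adult")
}
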