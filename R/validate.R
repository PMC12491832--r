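#' Reanalyse dual-reader data as if collected with a single reader
#'
#' Keeps only hits from the designated reader position per entrance (plus
#' any hits already marked \code{"only"}) and rewrites the reader field to
#' \code{"only"}, so the stream looks like single-reader-era data and all
#' derived passes have unknown direction. Idempotent.
#'
#' @param events detection events.
#' @param reader which physical reader to retain; default \code{"inner"}.
#' @return the filtered events, reader field set to \code{"only"}.
#' @export
single_reader_reanalysis <- function(events, reader = "inner") {
  keep <- events$reader %in% c(reader, "only")
  out <- events[keep, , drop = FALSE]
  out$reader <- rep("only", nrow(out))
  rownames(out) <- NULL
  out
}

#' End-date concordance between dual- and single-reader extractions
#'
#' Over the (tag, bat year) keys present in both phenology tables, the
#' per-species fraction of records whose hibernation end dates are exactly
#' equal.
#'
#' @param dual_records,single_records phenology tables from
#'   [compile_phenology()] in dual and single mode.
#' @return data frame per species: \code{species}, \code{n_compared},
#'   \code{fraction_identical}. With zero overlapping keys a single row with
#'   \code{n_compared = 0} and \code{fraction_identical = NA} is returned
#'   with a warning.
#' @export
end_date_concordance <- function(dual_records, single_records) {
  m <- merge(dual_records[, c("tag_id", "bat_year", "species", "end_date")],
             single_records[, c("tag_id", "bat_year", "end_date")],
             by = c("tag_id", "bat_year"), suffixes = c("_dual", "_single"))
  m <- m[!is.na(m$end_date_dual) & !is.na(m$end_date_single), , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no overlapping (tag, bat year) keys to compare", call. = FALSE)
    return(data.frame(species = NA_character_, n_compared = 0L,
                      fraction_identical = NA_real_))
  }
  same <- m$end_date_dual == m$end_date_single
  agg <- stats::aggregate(same, by = list(species = m$species),
                   FUN = function(z) c(n = length(z), frac = mean(z)))
  data.frame(species = agg$species, n_compared = as.integer(agg$x[, "n"]),
             fraction_identical = agg$x[, "frac"])
}

#' Final departure date of one individual-year
#'
#' Scans the confirmed exits after noon of the record's hibernation end bat
#' day, in time order, and returns the bat day of the first exit that is not
#' followed by an entry of the same tag within 24 hours (exact timestamps,
#' not calendar days). Used to check that extracted end dates reflect true
#' emergence.
#'
#' @param passes dual-mode passes of the record's tag and bat year, sorted
#'   by timestamp.
#' @param record one row of a dual-mode phenology table.
#' @return a \code{Date}, or \code{NULL} if no qualifying exit exists.
#' @export
final_departure <- function(passes, record) {
  if (is.null(record) || is.na(record$end_date)) return(NULL)
  noon <- as.POSIXct(paste(record$end_date, "12:00:00"), tz = "UTC")
  p <- passes[passes$timestamp >= noon, , drop = FALSE]
  exits <- which(p$direction == "exit")
  for (i in exits) {
    later_entry <- p$direction == "entry" &
      p$timestamp > p$timestamp[i] &
      p$timestamp <= p$timestamp[i] + 86400
    if (!any(later_entry)) return(bat_day(p$timestamp[i]))
  }
  NULL
}

#' Fraction of final departures close to the hibernation end date
#'
#' Among records with a non-null final departure, the per-species fraction
#' whose departure falls strictly less than \code{tolerance_days} bat days
#' after the hibernation end date.
#'
#' @param records dual-mode phenology table.
#' @param passes the pass table the records were extracted from.
#' @param tolerance_days strict upper bound in days; default 7 ("less than
#'   one week").
#' @return data frame per species: \code{species}, \code{n},
#'   \code{fraction_within}.
#' @export
departure_within <- function(records, passes, tolerance_days = 7) {
  grp <- split(passes, list(passes$tag_id, passes$bat_year), drop = TRUE)
  key <- paste(records$tag_id, records$bat_year, sep = ".")
  dep <- vapply(seq_len(nrow(records)), function(i) {
    g <- grp[[key[i]]]
    if (is.null(g)) return(NA_real_)
    fd <- final_departure(g, records[i, ])
    if (is.null(fd)) NA_real_ else as.numeric(fd - records$end_date[i])
  }, numeric(1))
  ok <- !is.na(dep)
  if (!any(ok)) {
    return(data.frame(species = unique(records$species), n = 0L,
                      fraction_within = NA_real_))
  }
  agg <- stats::aggregate(dep[ok] < tolerance_days,
                   by = list(species = records$species[ok]),
                   FUN = function(z) c(n = length(z), frac = mean(z)))
  data.frame(species = agg$species, n = as.integer(agg$x[, "n"]),
             fraction_within = agg$x[, "frac"])
}
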