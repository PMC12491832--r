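#' File formats
#'
#' All files are comma-separated UTF-8 with a header row; timestamps are
#' ISO-8601 at second resolution (\code{YYYY-MM-DDTHH:MM:SS}), treated as
#' timezone-naive local time (no DST arithmetic; phenology resolution is
#' daily). Dates are \code{YYYY-MM-DD}.
#'
#' \describe{
#'   \item{detections}{\code{timestamp, tag_id, entrance_id, reader}; reader
#'     is \code{inner}/\code{outer} for the dual-reader era or \code{only}
#'     for single-reader data.}
#'   \item{captures}{\code{tag_id, species, sex, age_at_tagging,
#'     tagging_date, forearm_mm, mass_g}; one row per tagged bat.}
#'   \item{weather}{\code{timestamp, temp_c}; hourly air temperature.}
#'   \item{exclusions}{\code{species, bat_year, variable}; species may be
#'     \code{"both"}, variable one of \code{start}, \code{end},
#'     \code{duration}.}
#' }
#' @name batphen-formats
NULL

TS_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FMT, tz = "UTC")
  # tolerate a space separator as well
  sp <- is.na(out) & !is.na(x)
  if (any(sp)) {
    out[sp] <- as.POSIXct(x[sp], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

format_ts <- function(x) format(x, TS_FMT)

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

# Abort if more than `frac` of rows are bad; otherwise drop them with a
# warning naming the offending line numbers (1-based data rows + header).
reject_rows <- function(df, bad, what, path, frac = 0.01) {
  if (!any(bad)) return(df)
  lines <- which(bad) + 1L
  msg <- paste0(sum(bad), " row(s) with ", what, " in '", path,
                "' (line ", paste(utils::head(lines, 10), collapse = ", "),
                if (sum(bad) > 10) ", ..." else "", ")")
  if (mean(bad) > frac) stop(msg, call. = FALSE)
  warning(msg, ", dropped", call. = FALSE)
  df[!bad, , drop = FALSE]
}

#' Read and validate an RFID detection log
#'
#' Malformed rows (unparseable timestamp, reader outside
#' \code{inner/outer/only}) are reported with their line numbers; the read
#' aborts if more than 1\% of rows are malformed, otherwise they are dropped
#' with a warning. Events are returned sorted by (tag_id, timestamp).
#'
#' @param path CSV path (see \link{batphen-formats}).
#' @return data frame of detection events.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("timestamp", "tag_id", "entrance_id", "reader"), path)
  if (nrow(df) == 0) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      tag_id = character(), entrance_id = integer(),
                      reader = character()))
  }
  ts <- parse_ts(df$timestamp)
  df <- reject_rows(df, is.na(ts), "unparseable timestamp", path)
  ts <- ts[!is.na(ts)]
  bad_reader <- !(df$reader %in% c("inner", "outer", "only"))
  keep <- !bad_reader
  df2 <- reject_rows(df, bad_reader, "invalid reader value", path)
  out <- data.frame(timestamp = ts[keep], tag_id = df2$tag_id,
                    entrance_id = as.integer(df2$entrance_id),
                    reader = df2$reader)
  out <- out[order(out$tag_id, out$timestamp, out$reader), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and validate capture/tagging records
#'
#' @param path CSV path (see \link{batphen-formats}).
#' @return data frame of capture records; duplicate \code{tag_id}s are an
#'   error.
#' @export
read_captures <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("tag_id", "species", "sex", "age_at_tagging",
                        "tagging_date", "forearm_mm", "mass_g"), path)
  dup <- unique(df$tag_id[duplicated(df$tag_id)])
  if (length(dup)) {
    stop("duplicate tag_id in '", path, "': ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  bad <- !(df$sex %in% c("F", "M")) |
    !(df$age_at_tagging %in% c("juvenile", "adult"))
  df <- reject_rows(df, bad, "invalid sex or age class", path)
  out <- data.frame(tag_id = df$tag_id, species = df$species, sex = df$sex,
                    age_at_tagging = df$age_at_tagging,
                    tagging_date = as.Date(df$tagging_date),
                    forearm_mm = as.numeric(df$forearm_mm),
                    mass_g = as.numeric(df$mass_g))
  if (nrow(out) > 0 && any(out$forearm_mm <= 0 | out$mass_g <= 0, na.rm = TRUE)) {
    stop("non-positive forearm_mm or mass_g in '", path, "'", call. = FALSE)
  }
  out
}

#' Read and validate an hourly weather series
#'
#' Duplicate timestamps keep the first sample (with a warning); gaps longer
#' than one hour are permitted but reported via \code{message()}.
#'
#' @param path CSV path (see \link{batphen-formats}).
#' @return data frame with \code{timestamp}, \code{temp_c}, strictly
#'   increasing in time.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("timestamp", "temp_c"), path)
  ts <- parse_ts(df$timestamp)
  df <- reject_rows(df, is.na(ts), "unparseable timestamp", path)
  ts <- ts[!is.na(ts)]
  o <- order(ts)
  ts <- ts[o]
  temp <- as.numeric(df$temp_c)[o]
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in '", path,
            "', keeping first", call. = FALSE)
    ts <- ts[!dup]
    temp <- temp[!dup]
  }
  gaps <- which(diff(as.numeric(ts)) > 3600)
  if (length(gaps)) {
    message(length(gaps), " gap(s) longer than one hour in '", path,
            "', largest ", round(max(diff(as.numeric(ts))) / 3600, 1), " h")
  }
  data.frame(timestamp = ts, temp_c = temp)
}

#' Read an exclusion list
#'
#' @param path CSV with columns \code{species} (a species label or
#'   \code{"both"}), \code{bat_year}, \code{variable} (\code{start},
#'   \code{end} or \code{duration}).
#' @return data frame of exclusion rules.
#' @export
read_exclusions <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("species", "bat_year", "variable"), path)
  bad <- !(df$variable %in% c("start", "end", "duration"))
  if (any(bad)) {
    stop("invalid exclusion variable(s) in '", path, "': ",
         paste(unique(df$variable[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(species = df$species, bat_year = as.integer(df$bat_year),
             variable = df$variable)
}

#' Write pipeline files
#'
#' CSV writers matching the readers (see \link{batphen-formats}); a
#' write/read round trip is the identity for all record kinds.
#'
#' @param x the records to write.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(x, path) {
  out <- data.frame(timestamp = format_ts(x$timestamp), tag_id = x$tag_id,
                    entrance_id = x$entrance_id, reader = x$reader)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_captures <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_weather <- function(x, path) {
  out <- data.frame(timestamp = format_ts(x$timestamp), temp_c = x$temp_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_truth <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-file QC report
#'
#' Reads each provided file through its validator and prints a short
#' quality-control summary (row counts, time span, distinct tags/species).
#'
#' @param detections,captures,weather,exclusions optional CSV paths.
#' @return invisibly, a list of the parsed tables.
#' @export
validate_files <- function(detections = NULL, captures = NULL,
                           weather = NULL, exclusions = NULL) {
  out <- list()
  if (!is.null(detections)) {
    d <- read_detections(detections)
    cat(sprintf("detections: %d events, %d tags, %s .. %s\n", nrow(d),
                length(unique(d$tag_id)), min(d$timestamp), max(d$timestamp)))
    out$detections <- d
  }
  if (!is.null(captures)) {
    cp <- read_captures(captures)
    cat(sprintf("captures: %d bats (%s)\n", nrow(cp),
                paste(sprintf("%s=%d", names(table(cp$species)),
                              table(cp$species)), collapse = ", ")))
    out$captures <- cp
  }
  if (!is.null(weather)) {
    w <- read_weather(weather)
    cat(sprintf("weather: %d hourly samples, %s .. %s, mean %.1f C\n",
                nrow(w), min(w$timestamp), max(w$timestamp), mean(w$temp_c)))
    out$weather <- w
  }
  if (!is.null(exclusions)) {
    ex <- read_exclusions(exclusions)
    cat(sprintf("exclusions: %d rule(s)\n", nrow(ex)))
    out$exclusions <- ex
  }
  invisible(out)
}
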