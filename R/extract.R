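#' Longest hibernation period of one individual in one bat year
#'
#' The operational definition of ecological hibernation: among the gaps
#' between consecutive passes of the focal bat year, the eligible gaps are
#' those opening on a bat day between 1 July and 1 February and closing on a
#' bat day between 31 December and 30 April (both windows inclusive); the
#' record is the eligible gap of maximal duration, ties broken by earliest
#' start. Gap endpoints are the bat days of the bounding passes themselves.
#'
#' In dual-reader mode the selected gap must additionally open with a
#' confirmed \code{entry} and close with a confirmed \code{exit}; if either
#' direction of the selected longest gap is not confirmed the record is
#' discarded (no fallback to shorter gaps).
#'
#' @param passes passes of one tag in one bat year, sorted by timestamp
#'   (as from [build_passes()]).
#' @param mode \code{"single"} (directions ignored) or \code{"dual"}.
#' @return a one-row data frame (\code{tag_id}, \code{bat_year},
#'   \code{start_date}, \code{end_date}, \code{duration_days}, \code{mode}),
#'   or \code{NULL} when no eligible gap exists or the dual-mode direction
#'   requirement fails.
#' @export
extract_longest_gap <- function(passes, mode = c("single", "dual")) {
  mode <- match.arg(mode)
  n <- nrow(passes)
  if (n < 2) return(NULL)
  if (is.unsorted(passes$timestamp)) {
    stop("passes must be sorted by timestamp", call. = FALSE)
  }
  yr <- passes$bat_year[1]
  w <- hib_windows(yr)
  d <- passes$bat_day
  i <- seq_len(n - 1L)
  eligible <- d[i] >= w$start_lo & d[i] <= w$start_hi &
    d[i + 1L] >= w$end_lo & d[i + 1L] <= w$end_hi
  dur <- as.integer(d[i + 1L] - d[i])
  eligible <- eligible & dur >= 1L
  if (!any(eligible)) return(NULL)
  cand <- which(eligible)
  best <- cand[which.max(dur[cand])]  # which.max takes the first maximum:
  # candidates are in time order, so ties resolve to the earliest start
  if (mode == "dual" &&
      (passes$direction[best] != "entry" ||
         passes$direction[best + 1L] != "exit")) {
    return(NULL)
  }
  data.frame(tag_id = passes$tag_id[1], bat_year = yr,
             start_date = d[best], end_date = d[best + 1L],
             duration_days = dur[best], mode = mode)
}

#' Mask excluded (species, bat year, variable) combinations
#'
#' Applies an exclusion list for known monitoring outages: each rule masks
#' the named variable (\code{start}, \code{end} or \code{duration}) for all
#' records of the matching species (or \code{"both"}) and bat year by
#' setting it to \code{NA}. Masking start or end also masks duration, since
#' duration is their difference. Unmatched records pass through unchanged;
#' the operation is idempotent.
#'
#' @param records phenology table as from [compile_phenology()].
#' @param rules data frame with columns \code{species}, \code{bat_year},
#'   \code{variable} (see [read_exclusions()]).
#' @return the table with masked fields set to \code{NA}.
#' @export
apply_exclusions <- function(records, rules) {
  if (is.null(rules) || nrow(rules) == 0 || nrow(records) == 0) {
    return(records)
  }
  for (i in seq_len(nrow(rules))) {
    hit <- records$bat_year == rules$bat_year[i] &
      (rules$species[i] == "both" | records$species == rules$species[i])
    if (!any(hit)) next
    v <- rules$variable[i]
    if (v == "start") {
      records$start_date[hit] <- as.Date(NA)
      if ("start_day_index" %in% names(records)) {
        records$start_day_index[hit] <- NA_integer_
      }
    } else if (v == "end") {
      records$end_date[hit] <- as.Date(NA)
      if ("end_day_index" %in% names(records)) {
        records$end_day_index[hit] <- NA_integer_
      }
    }
    records$duration_days[hit] <- NA_integer_
  }
  records
}

#' Compile the per-individual hibernation phenology table
#'
#' Runs [extract_longest_gap()] for every (tag, bat year) group of the pass
#' table, joins species/sex from the capture records, assigns the effective
#' age class (juveniles promoted to adult after their first bat year),
#' encodes start/end as day indices from 1 July of the bat year, and applies
#' the exclusion rules. Tags present in the passes but absent from the
#' captures are dropped with a warning. No outlier filtering is applied; all
#' extracted records are retained.
#'
#' @param passes pass table from [build_passes()].
#' @param captures capture records from [read_captures()] or the simulator.
#' @param rules optional exclusion rules (see [apply_exclusions()]).
#' @param mode \code{"single"} or \code{"dual"} extraction mode.
#' @return data frame with one row per (tag, bat year) having a non-null
#'   extraction: \code{tag_id}, \code{species}, \code{sex}, \code{age},
#'   \code{class}, \code{bat_year}, \code{start_date}, \code{end_date},
#'   \code{duration_days}, \code{start_day_index}, \code{end_day_index},
#'   \code{mode}.
#' @export
compile_phenology <- function(passes, captures, rules = NULL,
                              mode = c("single", "dual")) {
  mode <- match.arg(mode)
  empty <- data.frame(tag_id = character(), species = character(),
                      sex = character(), age = character(),
                      class = character(), bat_year = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration_days = integer(),
                      start_day_index = integer(), end_day_index = integer(),
                      mode = character())
  if (nrow(passes) == 0) return(empty)
  unknown <- setdiff(unique(passes$tag_id), captures$tag_id)
  if (length(unknown)) {
    warning(length(unknown), " tag(s) in passes missing from captures, ",
            "dropped: ", paste(utils::head(unknown, 5), collapse = ", "),
            call. = FALSE)
    passes <- passes[!(passes$tag_id %in% unknown), , drop = FALSE]
  }
  if (nrow(passes) == 0) return(empty)
  grp <- split(passes, list(passes$tag_id, passes$bat_year), drop = TRUE)
  recs <- lapply(grp, extract_longest_gap, mode = mode)
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) == 0) return(empty)
  ci <- match(recs$tag_id, captures$tag_id)
  recs$species <- captures$species[ci]
  recs$sex <- captures$sex[ci]
  recs$age <- effective_age(captures$age_at_tagging[ci],
                            captures$tagging_date[ci], recs$bat_year)
  recs$class <- paste(recs$age, recs$sex)
  recs$start_day_index <- day_index(recs$start_date, recs$bat_year)
  recs$end_day_index <- day_index(recs$end_date, recs$bat_year)
  recs <- recs[order(recs$tag_id, recs$bat_year), , drop = FALSE]
  rownames(recs) <- NULL
  recs <- recs[, names(empty)]
  apply_exclusions(recs, rules)
}
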