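# Independent brute-force oracle for the longest-hibernation-period
# definition, written as a plain loop over consecutive pass pairs with
# literal window dates, deliberately sharing no code with the package.
brute_longest_gap <- function(passes, mode = "single") {
  n <- nrow(passes)
  if (n < 2) return(NULL)
  yr <- passes$bat_year[1]
  start_lo <- as.Date(sprintf("%d-07-01", yr))
  start_hi <- as.Date(sprintf("%d-02-01", yr + 1))
  end_lo <- as.Date(sprintf("%d-12-31", yr))
  end_hi <- as.Date(sprintf("%d-04-30", yr + 1))
  best <- NULL
  best_dur <- 0
  for (i in 1:(n - 1)) {
    d1 <- passes$bat_day[i]
    d2 <- passes$bat_day[i + 1]
    dur <- as.numeric(d2 - d1)
    if (d1 < start_lo || d1 > start_hi) next
    if (d2 < end_lo || d2 > end_hi) next
    if (dur < 1) next
    if (dur > best_dur) {  # strict: ties keep the earlier start
      best_dur <- dur
      best <- i
    }
  }
  if (is.null(best)) return(NULL)
  if (mode == "dual") {
    if (passes$direction[best] != "entry" ||
        passes$direction[best + 1] != "exit") {
      return(NULL)
    }
  }
  list(start = passes$bat_day[best], end = passes$bat_day[best + 1],
       duration = best_dur)
}

# random pass stream of one tag confined to one bat year
random_pass_stream <- function(year = 2018, max_passes = 10) {
  n <- sample(0:max_passes, 1)
  if (n == 0) {
    return(data.frame(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      entrance_id = integer(), direction = character(),
                      bat_day = as.Date(character()), bat_year = integer()))
  }
  t0 <- as.POSIXct(sprintf("%d-07-01 12:00:00", year), tz = "UTC")
  ts <- sort(t0 + round(runif(n, 0, 364 * 86400)))
  p <- data.frame(tag_id = "t1", timestamp = ts,
                  entrance_id = sample(3L, n, replace = TRUE),
                  direction = sample(c("entry", "exit", "unknown"), n,
                                     replace = TRUE,
                                     prob = c(0.4, 0.4, 0.2)))
  p$bat_day <- bat_day(p$timestamp)
  p$bat_year <- rep(year, n)
  p
}

expect_gap_equal <- function(got, want) {
  if (is.null(want)) {
    expect_null(got)
  } else {
    expect_false(is.null(got))
    expect_equal(got$start_date, want$start)
    expect_equal(got$end_date, want$end)
    expect_equal(got$duration_days, want$duration)
  }
}
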