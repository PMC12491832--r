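#' Simulation configuration for synthetic RFID detection streams
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The generator emulates a multi-year RFID monitoring study at a single
#' hibernaculum: cohorts of newly tagged bats each year, class-specific
#' hibernation entry/end schedules with linear year trends and a temperature
#' sensitivity of entry, individual random intercepts, autumn swarming
#' visits, rare brief mid-winter exits, per-reader detection failure and
#' power outages.
#'
#' Defaults describe a 13-bat-year study (2010--2022) of two species
#' (\emph{Myotis daubentonii}, \emph{M. nattereri}) with up to 150 newly
#' tagged individuals per species per year, class schedules giving
#' \emph{M. daubentonii} a roughly six-month and \emph{M. nattereri} a
#' roughly three-month hibernation period, and per-class year trends and
#' temperature effects of the magnitude reported for this system.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param species character vector of species labels.
#' @param years strictly increasing integer bat-year labels.
#' @param n_new_tags_per_year_per_species cohort size tagged each autumn.
#' @param class_effects data frame with columns \code{species}, \code{class}
#'   (one of \code{"adult F"}, \code{"adult M"}, \code{"juvenile F"},
#'   \code{"juvenile M"}), \code{baseline_entry}, \code{baseline_end}
#'   (day-of-bat-year, days since 1 July, entry < end), \code{entry_trend},
#'   \code{end_trend} (days/year), \code{temp_effect_entry},
#'   \code{temp_effect_end} (days/degree C). Defaults from
#'   \code{default_class_effects()}.
#' @param individual_sd sd (days) of the per-individual random intercept.
#' @param residual_sd sd (days) of the per-individual-year residual.
#' @param annual_survival per-year survival probability in (0, 1].
#' @param swarming_visits_mean expected number of pre-entry swarming visit
#'   nights (Poisson).
#' @param winter_exit_prob per-winter probability of one brief mid-winter
#'   exit/re-entry pair.
#' @param p_detect per-reader per-pass detection probability in (0, 1].
#' @param crossing_seconds typical inner-outer traversal time of the gate.
#' @param outages data frame with POSIXct columns \code{start}, \code{end};
#'   all reader hits inside an outage window are lost.
#' @param juvenile_fraction,female_fraction composition of tagged cohorts.
#' @param weather list with elements \code{mean_c} (annual mean, degree C),
#'   \code{amplitude_c} (seasonal sinusoid half-range), \code{warming_c_per_year},
#'   \code{noise_sd_c} (hourly i.i.d. noise) and \code{annual_anomaly_sd_c}
#'   (per-calendar-year mean anomaly, the dominant source of year-to-year
#'   variation in two-month window medians).
#' @return a validated list of class \code{"sim_config"}.
#' @seealso [simulate_dataset()] for the one-call generator.
#' @export
sim_config <- function(seed,
                       species = c("daubentonii", "nattereri"),
                       years = 2010:2022,
                       n_new_tags_per_year_per_species = 150,
                       class_effects = default_class_effects(),
                       individual_sd = 5,
                       residual_sd = 5,
                       annual_survival = 0.8,
                       swarming_visits_mean = 2,
                       winter_exit_prob = 0.05,
                       p_detect = 0.98,
                       crossing_seconds = 10,
                       outages = NULL,
                       juvenile_fraction = 0.5,
                       female_fraction = 0.5,
                       weather = list(mean_c = 10, amplitude_c = 8,
                                      warming_c_per_year = 0.05,
                                      noise_sd_c = 3,
                                      annual_anomaly_sd_c = 0.8)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("'seed' is mandatory and must be a single integer", call. = FALSE)
  }
  if (length(years) == 0) stop("'years' must be non-empty", call. = FALSE)
  if (any(diff(years) <= 0)) {
    stop("'years' must be strictly increasing", call. = FALSE)
  }
  probs <- c(annual_survival = annual_survival, p_detect = p_detect,
             winter_exit_prob = winter_exit_prob,
             juvenile_fraction = juvenile_fraction,
             female_fraction = female_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities out of [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (annual_survival <= 0 || p_detect < 0) {
    stop("'annual_survival' must be in (0, 1]", call. = FALSE)
  }
  ce <- as.data.frame(class_effects)
  need <- c("species", "class", "baseline_entry", "baseline_end",
            "entry_trend", "end_trend", "temp_effect_entry",
            "temp_effect_end")
  miss <- setdiff(need, names(ce))
  if (length(miss)) {
    stop("class_effects missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(ce$baseline_entry >= ce$baseline_end)) {
    stop("baseline entry day must precede baseline end day for every class",
         call. = FALSE)
  }
  miss_cls <- setdiff(as.vector(outer(species, sexage_classes(), paste,
                                      sep = ":")),
                      paste(ce$species, ce$class, sep = ":"))
  if (length(miss_cls)) {
    stop("class_effects lacks rows for: ", paste(miss_cls, collapse = ", "),
         call. = FALSE)
  }
  wdef <- list(mean_c = 10, amplitude_c = 8, warming_c_per_year = 0.05,
               noise_sd_c = 3, annual_anomaly_sd_c = 0.8)
  weather <- utils::modifyList(wdef, weather)
  if (is.null(outages)) {
    outages <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"))
  }
  structure(list(seed = as.integer(seed), species = species,
                 years = as.integer(years),
                 n_new_tags_per_year_per_species =
                   as.integer(n_new_tags_per_year_per_species),
                 class_effects = ce, individual_sd = individual_sd,
                 residual_sd = residual_sd, annual_survival = annual_survival,
                 swarming_visits_mean = swarming_visits_mean,
                 winter_exit_prob = winter_exit_prob, p_detect = p_detect,
                 crossing_seconds = crossing_seconds, outages = outages,
                 juvenile_fraction = juvenile_fraction,
                 female_fraction = female_fraction, weather = weather),
            class = "sim_config")
}

#' The four sex-age classes
#' @return character vector of class labels in canonical order.
#' @export
sexage_classes <- function() {
  c("adult F", "adult M", "juvenile F", "juvenile M")
}

#' Default per-class schedule parameters
#'
#' Baseline entry/end days (days since 1 July), linear year trends
#' (days/year) and entry-temperature sensitivities (days/degree C) for the
#' two species. Baselines put \emph{M. daubentonii} entry in early October
#' and emergence in early April (about six months hibernation) and
#' \emph{M. nattereri} entry in early December and emergence in early March
#' (about three months). Trend and temperature-effect magnitudes follow the
#' per-class estimates reported for this hibernaculum system.
#'
#' @return data frame usable as the \code{class_effects} argument of
#'   [sim_config()].
#' @export
default_class_effects <- function() {
  cls <- sexage_classes()
  rbind(
    data.frame(species = "daubentonii", class = cls,
               baseline_entry = c(95, 90, 105, 110),
               baseline_end = c(275, 273, 270, 268),
               entry_trend = c(-0.97, -2.14, -0.70, -0.65),
               end_trend = c(-0.20, -0.16, 0.19, 0.81),
               temp_effect_entry = c(-6.69, -9.25, -4.15, -1.07),
               temp_effect_end = 0),
    data.frame(species = "nattereri", class = cls,
               baseline_entry = c(160, 158, 168, 170),
               baseline_end = c(248, 246, 252, 250),
               entry_trend = c(0.54, 1.63, 1.72, 1.08),
               end_trend = c(-0.95, -0.54, -0.24, -0.62),
               temp_effect_entry = c(1.35, 6.15, 5.71, 4.79),
               temp_effect_end = 0)
  )
}

# independent sub-seed per generator stage, kept under 2^31
sub_seed <- function(seed, k) (as.numeric(seed) * 7L + k * 104729) %% 2147483647

#' Simulate an hourly air-temperature series
#'
#' One sample per hour covering every configured bat year (1 July of the
#' first through 30 June following the last). Temperature is an annual mean
#' plus a seasonal sinusoid peaking in mid-July, a linear warming trend, a
#' per-calendar-year anomaly and hourly Gaussian noise. Reproducible under a
#' fixed config seed.
#'
#' @param config a [sim_config()].
#' @return data frame with columns \code{timestamp} (POSIXct, hourly) and
#'   \code{temp_c}.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$years) == 0) stop("no years configured", call. = FALSE)
  set.seed(sub_seed(config$seed, 1))
  w <- config$weather
  t0 <- as.POSIXct(paste0(min(config$years), "-07-01 00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste0(max(config$years) + 1L, "-06-30 23:00:00"),
                   tz = "UTC")
  ts <- seq(t0, t1, by = 3600)
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + lt$hour / 24
  elapsed_years <- as.numeric(difftime(ts, t0, units = "days")) / 365.25
  cal_year <- lt$year + 1900L
  yrs <- sort(unique(cal_year))
  anom <- stats::rnorm(length(yrs), 0, w$annual_anomaly_sd_c)
  names(anom) <- as.character(yrs)
  temp <- w$mean_c +
    w$amplitude_c * cos(2 * pi * (doy - 196) / 365.25) +
    w$warming_c_per_year * elapsed_years +
    anom[as.character(cal_year)] +
    stats::rnorm(length(ts), 0, w$noise_sd_c)
  data.frame(timestamp = ts, temp_c = as.numeric(temp))
}

# deviation of each bat year's entry/end window median from the long-run mean
window_deviation <- function(weather, species, response, years) {
  win <- default_temp_windows()
  win <- win[win$species == species & win$response == response, ]
  med <- vapply(years, function(y) {
    median_window_temperature(weather, c(win$month1, win$month2), y)
  }, numeric(1))
  med - mean(med)
}

#' Simulate true hibernation schedules and capture records
#'
#' Draws the ground truth the detection stream is rendered from. Each bat
#' receives an individual intercept ~ Normal(0, \code{individual_sd}); for
#' each bat year it survives to, its true entry day is
#' class baseline + entry trend x (year - first year) + temperature effect x
#' (entry-window median deviation) + intercept + Normal(0,
#' \code{residual_sd}), rounded half-up to a whole day; the true exit day is
#' analogous (temperature term only if \code{temp_effect_end} is set).
#' Individuals tagged as juveniles are juveniles in their tagging bat year
#' and adults thereafter. Survival is a per-year Bernoulli; dead bats emit
#' nothing. Entry/exit pairs violating entry < exit are redrawn up to ten
#' times, then clamped (with a message).
#'
#' @param config a [sim_config()].
#' @param weather hourly series from [simulate_weather()].
#' @return list of class \code{"hib_schedules"} with elements \code{truth}
#'   (one row per surviving individual-year: tag_id, bat_year, species, sex,
#'   age, class, true_entry_date, true_exit_date, winter_exit_date),
#'   \code{captures} (one row per tagged bat) and \code{visits} (swarming
#'   visit nights: tag_id, bat_year, date).
#' @export
simulate_schedules <- function(config, weather) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2))
  years <- config$years
  y0 <- years[1]
  n <- config$n_new_tags_per_year_per_species

  roster <- expand.grid(species = config$species, tag_year = years,
                        idx = seq_len(n), stringsAsFactors = FALSE)
  roster <- roster[order(roster$species, roster$tag_year, roster$idx), ]
  nb <- nrow(roster)
  roster$tag_id <- sprintf("%s-%d-%03d", substr(roster$species, 1, 4),
                           roster$tag_year, roster$idx)
  roster$sex <- ifelse(stats::runif(nb) < config$female_fraction, "F", "M")
  roster$age_at_tagging <- ifelse(stats::runif(nb) < config$juvenile_fraction,
                                  "juvenile", "adult")
  # tagged during the August--September capture season
  roster$tagging_date <- bat_year_origin(roster$tag_year) +
    sample(45:91, nb, replace = TRUE)
  is_daub <- roster$species == "daubentonii"
  roster$forearm_mm <- round(stats::rnorm(nb, ifelse(is_daub, 37, 39),
                                          ifelse(is_daub, 1, 1.2)), 1)
  roster$mass_g <- round(stats::rnorm(nb, ifelse(is_daub, 8, 9), 0.8) * 2) / 2
  roster$intercept <- stats::rnorm(nb, 0, config$individual_sd)
  # years survived beyond the tagging year (geometric in annual survival)
  extra <- if (config$annual_survival >= 1) {
    rep(length(years), nb)
  } else {
    stats::rgeom(nb, 1 - config$annual_survival)
  }
  roster$last_year <- pmin(roster$tag_year + extra, max(years))

  captures <- roster[, c("tag_id", "species", "sex", "age_at_tagging",
                         "tagging_date", "forearm_mm", "mass_g")]
  rownames(captures) <- NULL

  nyr <- roster$last_year - roster$tag_year + 1L
  tr <- roster[rep(seq_len(nb), nyr), ]
  tr$bat_year <- unlist(lapply(seq_len(nb), function(i) {
    seq.int(roster$tag_year[i], roster$last_year[i])
  }), use.names = FALSE)
  tr$age <- ifelse(tr$age_at_tagging == "juvenile" &
                     tr$bat_year == tr$tag_year, "juvenile", "adult")
  tr$class <- paste(tr$age, tr$sex)

  ce <- config$class_effects
  key <- match(paste(tr$species, tr$class), paste(ce$species, ce$class))
  m <- nrow(tr)

  tr$dev_start <- 0
  tr$dev_end <- 0
  dev <- matrix(0, length(years), 2,
                dimnames = list(as.character(years), c("start", "end")))
  for (sp in config$species) {
    dev[, "start"] <- window_deviation(weather, sp, "start", years)
    dev[, "end"] <- window_deviation(weather, sp, "end", years)
    sel <- tr$species == sp
    tr$dev_start[sel] <- dev[as.character(tr$bat_year[sel]), "start"]
    tr$dev_end[sel] <- dev[as.character(tr$bat_year[sel]), "end"]
  }

  mu_entry <- ce$baseline_entry[key] + ce$entry_trend[key] * (tr$bat_year - y0) +
    ce$temp_effect_entry[key] * tr$dev_start + tr$intercept
  mu_end <- ce$baseline_end[key] + ce$end_trend[key] * (tr$bat_year - y0) +
    ce$temp_effect_end[key] * tr$dev_end + tr$intercept
  entry <- mu_entry + stats::rnorm(m, 0, config$residual_sd)
  end <- mu_end + stats::rnorm(m, 0, config$residual_sd)
  for (try in seq_len(10)) {
    bad <- which(floor(entry + 0.5) >= floor(end + 0.5))
    if (!length(bad)) break
    entry[bad] <- mu_entry[bad] + stats::rnorm(length(bad), 0,
                                               config$residual_sd)
    end[bad] <- mu_end[bad] + stats::rnorm(length(bad), 0, config$residual_sd)
  }
  entry_day <- floor(entry + 0.5)
  end_day <- floor(end + 0.5)
  bad <- entry_day >= end_day
  if (any(bad)) {
    message(sum(bad), " schedule(s) clamped to entry = exit - 1 after retries")
    entry_day[bad] <- end_day[bad] - 1
  }
  # keep truth inside the phenology windows the extractor searches
  origin <- bat_year_origin(tr$bat_year)
  end_hi <- as.integer(as.Date(paste0(tr$bat_year + 1L, "-04-30")) - origin)
  clamped <- sum(entry_day < 0 | entry_day > 215 |
                   end_day < 183 | end_day > end_hi)
  if (clamped > 0) {
    message(clamped, " schedule endpoint(s) clamped into the phenology windows")
  }
  entry_day <- pmax(0, pmin(entry_day, 215))
  end_day <- pmax(183, pmin(end_day, end_hi))
  tr$true_entry_date <- origin + entry_day
  tr$true_exit_date <- origin + end_day

  tr$winter_exit_date <- as.Date(NA)
  span <- as.integer(tr$true_exit_date - tr$true_entry_date)
  we <- stats::runif(m) < config$winter_exit_prob & span > 45
  if (any(we)) {
    off <- 20 + floor(stats::runif(sum(we)) * (span[we] - 40))
    tr$winter_exit_date[we] <- tr$true_entry_date[we] + off
  }

  nvis <- stats::rpois(m, config$swarming_visits_mean)
  vi <- rep(seq_len(m), nvis)
  visits <- data.frame(
    tag_id = tr$tag_id[vi], bat_year = tr$bat_year[vi],
    date = tr$true_entry_date[vi] - sample(30, length(vi), replace = TRUE)
  )
  visits <- unique(visits)

  truth <- tr[, c("tag_id", "bat_year", "species", "sex", "age", "class",
                  "true_entry_date", "true_exit_date", "winter_exit_date")]
  rownames(truth) <- NULL
  structure(list(truth = truth, captures = captures, visits = visits),
            class = "hib_schedules")
}

#' Render true schedules into an RFID detection stream
#'
#' Each true entry becomes an outer-then-inner reader hit pair and each true
#' exit an inner-then-outer pair, separated by \code{crossing_seconds};
#' crossing times are drawn within the night (18:00--06:00) of the scheduled
#' bat day. Each swarming visit night contributes an entry followed by an
#' exit within the same night; a mid-winter exit contributes an exit/re-entry
#' pair. Every reader hit is then independently dropped with probability
#' 1 - \code{p_detect}, and hits inside any configured outage window are
#' deleted.
#'
#' @param schedules result of [simulate_schedules()].
#' @param config the same [sim_config()].
#' @return detection events: data frame with columns \code{timestamp},
#'   \code{tag_id}, \code{entrance_id}, \code{reader} (\code{"inner"} or
#'   \code{"outer"}), sorted by timestamp.
#' @export
render_detections <- function(schedules, config) {
  stopifnot(inherits(schedules, "hib_schedules"),
            inherits(config, "sim_config"))
  tr <- schedules$truth
  if (nrow(tr) == 0) stop("no schedules to render", call. = FALSE)
  set.seed(sub_seed(config$seed, 3))

  night_ts <- function(date, lo = 18, hi = 30) {
    as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) +
                 stats::runif(length(date), lo, hi) * 3600,
               tz = "UTC", origin = "1970-01-01")
  }
  crossing <- function(tag, ts, dir) {
    # entry: outer then inner; exit: inner then outer
    first <- if (dir == "entry") "outer" else "inner"
    second <- if (dir == "entry") "inner" else "outer"
    n <- length(ts)
    ent <- sample(3L, n, replace = TRUE)
    data.frame(
      timestamp = c(ts, ts + config$crossing_seconds),
      tag_id = c(tag, tag), entrance_id = c(ent, ent),
      reader = c(rep(first, n), rep(second, n))
    )
  }

  parts <- list(
    crossing(tr$tag_id, night_ts(tr$true_entry_date), "entry"),
    crossing(tr$tag_id, night_ts(tr$true_exit_date), "exit")
  )
  vs <- schedules$visits
  if (!is.null(vs) && nrow(vs) > 0) {
    t1 <- night_ts(vs$date, 18, 25)
    t2 <- t1 + stats::runif(nrow(vs), 0.5, 4) * 3600
    parts <- c(parts, list(crossing(vs$tag_id, t1, "entry"),
                           crossing(vs$tag_id, t2, "exit")))
  }
  we <- tr[!is.na(tr$winter_exit_date), ]
  if (nrow(we) > 0) {
    t1 <- night_ts(we$winter_exit_date, 18, 25)
    t2 <- t1 + stats::runif(nrow(we), 0.5, 2) * 3600
    parts <- c(parts, list(crossing(we$tag_id, t1, "exit"),
                           crossing(we$tag_id, t2, "entry")))
  }
  ev <- do.call(rbind, parts)
  keep <- stats::runif(nrow(ev)) < config$p_detect
  ev <- ev[keep, , drop = FALSE]
  out <- config$outages
  if (!is.null(out) && nrow(out) > 0) {
    inside <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(out))) {
      inside <- inside | (ev$timestamp >= out$start[i] &
                            ev$timestamp <= out$end[i])
    }
    ev <- ev[!inside, , drop = FALSE]
  }
  ev <- ev[order(ev$timestamp, ev$tag_id, ev$reader), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: weather, true schedules, capture records and the
#' rendered detection stream, all driven by one configuration.
#'
#' @param config a [sim_config()].
#' @return list with elements \code{config}, \code{weather}, \code{truth},
#'   \code{captures}, \code{visits}, \code{detections}.
#' @examples
#' cfg <- sim_config(seed = 1, years = 2018:2020,
#'                   n_new_tags_per_year_per_species = 5)
#' d <- simulate_dataset(cfg)
#' head(d$detections)
#' @export
simulate_dataset <- function(config) {
  weather <- simulate_weather(config)
  sch <- simulate_schedules(config, weather)
  det <- render_detections(sch, config)
  list(config = config, weather = weather, truth = sch$truth,
       captures = sch$captures, visits = sch$visits, detections = det)
}
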