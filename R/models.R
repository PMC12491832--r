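#' Species-specific two-month temperature windows
#'
#' The climate covariate of the phenology models is the median air
#' temperature over a two-month period prior to and including the species'
#' median hibernation start or end date: August--September (start) and
#' February--March (end) for \emph{M. daubentonii}; November--December
#' (start) and January--February (end) for \emph{M. nattereri}.
#'
#' @return data frame with columns \code{species}, \code{response}
#'   (\code{start}/\code{end}), \code{month1}, \code{month2}.
#' @export
default_temp_windows <- function() {
  data.frame(
    species = c("daubentonii", "daubentonii", "nattereri", "nattereri"),
    response = c("start", "end", "start", "end"),
    month1 = c(8L, 2L, 11L, 1L),
    month2 = c(9L, 3L, 12L, 2L)
  )
}

# calendar year in which a window month of a given bat year falls:
# July-December belong to the bat year's own calendar year, January-June to
# the following one
window_calendar_year <- function(month, year) {
  ifelse(month >= 7L, year, year + 1L)
}

#' Median temperature of a two-month window within a bat year
#'
#' Median over all hourly samples whose timestamps fall inside the two
#' calendar months, each month resolved to the calendar year it occupies
#' within the bat year (e.g. Aug--Sep of bat year 2015 is Aug--Sep 2015;
#' Feb--Mar is Feb--Mar 2016).
#'
#' @param weather hourly series (\code{timestamp}, \code{temp_c}).
#' @param months integer vector of two consecutive calendar months.
#' @param year bat-year label.
#' @return the median temperature in degree C.
#' @export
median_window_temperature <- function(weather, months, year) {
  stopifnot(length(months) == 2)
  if (!(months[2] == months[1] + 1L ||
          (months[1] == 12L && months[2] == 1L))) {
    stop("window months must be consecutive", call. = FALSE)
  }
  lt <- as.POSIXlt(weather$timestamp)
  mo <- lt$mon + 1L
  cy <- lt$year + 1900L
  want <- (mo == months[1] & cy == window_calendar_year(months[1], year)) |
    (mo == months[2] & cy == window_calendar_year(months[2], year))
  if (!any(want)) {
    stop(sprintf("no weather samples in window %d-%d of bat year %d",
                 months[1], months[2], year), call. = FALSE)
  }
  stats::median(weather$temp_c[want])
}

#' Window median temperatures for every species, response and bat year
#'
#' @param weather hourly series.
#' @param years bat-year labels.
#' @param windows window definitions as [default_temp_windows()].
#' @return data frame: \code{species}, \code{response}, \code{bat_year},
#'   \code{median_c}.
#' @export
window_temperature_table <- function(weather, years,
                                     windows = default_temp_windows()) {
  out <- expand.grid(bat_year = years, wi = seq_len(nrow(windows)))
  out$species <- windows$species[out$wi]
  out$response <- windows$response[out$wi]
  out$median_c <- mapply(function(wi, y) {
    median_window_temperature(weather,
                              c(windows$month1[wi], windows$month2[wi]), y)
  }, out$wi, out$bat_year)
  out[, c("species", "response", "bat_year", "median_c")]
}

#' Collinearity of median, maximum and minimum window temperatures
#'
#' For each window and bat year, summarises the hourly series as the median
#' of all hourly samples and the maximum and minimum of the daily mean
#' temperatures, then reports the Pearson correlation of the median with
#' each extreme across bat years. Used to justify retaining the median as a
#' parsimonious covariate.
#'
#' @inheritParams window_temperature_table
#' @return data frame per window: \code{species}, \code{response},
#'   \code{r_median_max}, \code{r_median_min}; a constant summary series
#'   gives \code{NA} with a warning.
#' @export
temperature_collinearity <- function(weather, years,
                                     windows = default_temp_windows()) {
  if (length(years) < 3) {
    stop("need at least 3 bat years for a correlation", call. = FALSE)
  }
  lt <- as.POSIXlt(weather$timestamp)
  mo <- lt$mon + 1L
  cy <- lt$year + 1900L
  day <- as.Date(format(weather$timestamp, "%Y-%m-%d"))
  res <- lapply(seq_len(nrow(windows)), function(wi) {
    ms <- c(windows$month1[wi], windows$month2[wi])
    summ <- vapply(years, function(y) {
      want <- (mo == ms[1] & cy == window_calendar_year(ms[1], y)) |
        (mo == ms[2] & cy == window_calendar_year(ms[2], y))
      daily <- tapply(weather$temp_c[want], day[want], mean)
      c(med = stats::median(weather$temp_c[want]),
        mx = max(daily), mn = min(daily))
    }, numeric(3))
    r <- function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant temperature summary series; correlation undefined",
                call. = FALSE)
        return(NA_real_)
      }
      stats::cor(a, b)
    }
    data.frame(species = windows$species[wi], response = windows$response[wi],
               r_median_max = r(summ["med", ], summ["mx", ]),
               r_median_min = r(summ["med", ], summ["mn", ]))
  })
  do.call(rbind, res)
}

response_column <- function(response) {
  switch(response, start = "start_day_index", end = "end_day_index",
         duration = "duration_days",
         stop("unknown response '", response, "'", call. = FALSE))
}

# Per-class marginal slopes of `xvar` from a fit of resp ~ xvar * class.
# Slopes are obtained as fixed-effect finite differences (design row at
# xvar + 1 minus design row at xvar, per class), which is invariant to the
# contrast coding of the class factor. Wald normal inference.
marginal_slopes <- function(fit, xvar, classes) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  form <- if (length(classes) > 1) {
    stats::as.formula(paste("~", xvar, "* class"))
  } else {
    stats::as.formula(paste("~", xvar))
  }
  L <- t(vapply(classes, function(k) {
    nd <- data.frame(x = c(0, 1), class = factor(k, levels = classes))
    names(nd)[1] <- xvar
    X <- stats::model.matrix(form, nd)
    X[2, ] - X[1, ]
  }, numeric(length(b))))
  L <- rbind(L, overall = colMeans(L))
  slope <- as.numeric(L %*% b)
  se <- sqrt(rowSums((L %*% V) * L))
  t <- slope / se
  data.frame(class = c(classes, "overall"), slope = slope, se = se, t = t,
             p = 2 * stats::pnorm(-abs(t)), row.names = NULL)
}

fit_one_species <- function(df, xvar, random) {
  df$class <- droplevels(df$class)
  classes <- levels(df$class)
  fixed <- if (length(classes) > 1) {
    paste("resp ~", xvar, "* class")
  } else {
    paste("resp ~", xvar)
  }
  fallback <- FALSE
  fit <- tryCatch({
    f <- lme4::lmer(stats::as.formula(paste0(fixed, " + (1 | ", random, ")")),
                    data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
    if (lme4::isSingular(f)) stop("singular fit")
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed model singular or failed; falling back to fixed effects",
            call. = FALSE)
    fallback <- TRUE
    fit <- stats::lm(stats::as.formula(fixed), data = df)
  }
  sl <- marginal_slopes(fit, xvar, classes)
  list(fit = fit, slopes = sl, fallback = fallback)
}

#' Year trends in hibernation phenology by sex-age class
#'
#' Fits, separately per species, a linear mixed model of the chosen
#' phenology response (start or end day index, or duration in days) with
#' fixed effects for the centred bat year, the four-level sex-age class and
#' their interaction, and a random intercept per individual; estimation by
#' REML. Per-class marginal slopes (days/year) are derived from the
#' interaction structure; the \code{overall} slope is the unweighted mean of
#' the class slopes. Inference is Wald with a normal reference. A singular
#' or failed mixed fit falls back to the fixed-effects model with a warning
#' and a flag.
#'
#' @param phenology phenology table from [compile_phenology()].
#' @param response \code{"start"}, \code{"end"} or \code{"duration"}.
#' @return object of class \code{"hib_trend"}; \code{coef()} returns the
#'   slope table (species, class, response, slope, se, t, p).
#' @examples
#' cfg <- sim_config(seed = 42, years = 2015:2020,
#'                   n_new_tags_per_year_per_species = 40,
#'                   swarming_visits_mean = 0, winter_exit_prob = 0,
#'                   p_detect = 1)
#' d <- simulate_dataset(cfg)
#' passes <- build_passes(d$detections)
#' phen <- compile_phenology(passes, d$captures, mode = "dual")
#' fit <- fit_year_trend(phen, "start")
#' coef(fit)
#' @export
fit_year_trend <- function(phenology, response = c("start", "end",
                                                   "duration")) {
  response <- match.arg(response)
  col <- response_column(response)
  phen <- phenology[!is.na(phenology[[col]]), , drop = FALSE]
  if (nrow(phen) == 0) stop("no unmasked records to fit", call. = FALSE)
  y0 <- min(phen$bat_year)
  species <- sort(unique(phen$species))
  fits <- list()
  slopes <- list()
  for (sp in species) {
    df <- phen[phen$species == sp, , drop = FALSE]
    if (length(unique(df$bat_year)) < 2) {
      stop("species '", sp, "': need records from at least 2 bat years",
           call. = FALSE)
    }
    df <- data.frame(resp = df[[col]], year_c = df$bat_year - y0,
                     class = factor(df$class, levels = sexage_classes()),
                     tag_id = df$tag_id)
    r <- fit_one_species(df, "year_c", "tag_id")
    r$slopes$species <- sp
    r$slopes$response <- response
    fits[[sp]] <- r$fit
    attr(fits[[sp]], "fallback") <- r$fallback
    slopes[[sp]] <- r$slopes
  }
  out <- do.call(rbind, slopes)
  rownames(out) <- NULL
  structure(list(type = "year", unit = "days/year", response = response,
                 slopes = out[, c("species", "class", "response", "slope",
                                  "se", "t", "p")],
                 fits = fits),
            class = "hib_trend")
}

#' Temperature effects on hibernation phenology by sex-age class
#'
#' Fits, separately per species, a linear mixed model of the start or end
#' day index with fixed effects for the species-specific two-month window
#' median temperature, the sex-age class and their interaction, and a
#' random intercept per bat year. Per-class marginal effects are in
#' days/degree C. Refuses to fit with fewer than 3 distinct window
#' temperatures.
#'
#' @param phenology phenology table from [compile_phenology()].
#' @param weather hourly temperature series covering all bat years.
#' @param response \code{"start"} or \code{"end"}.
#' @param windows window definitions, default [default_temp_windows()].
#' @return object of class \code{"hib_trend"} (unit days/degree C).
#' @export
fit_temperature_model <- function(phenology, weather,
                                  response = c("start", "end"),
                                  windows = default_temp_windows()) {
  response <- match.arg(response)
  col <- response_column(response)
  phen <- phenology[!is.na(phenology[[col]]), , drop = FALSE]
  if (nrow(phen) == 0) stop("no unmasked records to fit", call. = FALSE)
  years <- sort(unique(phen$bat_year))
  tw <- window_temperature_table(weather, years, windows)
  tw <- tw[tw$response == response, ]
  species <- sort(unique(phen$species))
  fits <- list()
  slopes <- list()
  for (sp in species) {
    df <- phen[phen$species == sp, , drop = FALSE]
    tsp <- tw[tw$species == sp, ]
    temp <- tsp$median_c[match(df$bat_year, tsp$bat_year)]
    if (any(is.na(temp))) {
      stop("species '", sp, "': missing window temperature for some bat year",
           call. = FALSE)
    }
    if (length(unique(round(temp, 6))) < 3) {
      stop("species '", sp, "': fewer than 3 distinct window temperatures",
           call. = FALSE)
    }
    df <- data.frame(resp = df[[col]], temp_c = temp,
                     class = factor(df$class, levels = sexage_classes()),
                     bat_year_f = factor(df$bat_year))
    r <- fit_one_species(df, "temp_c", "bat_year_f")
    r$slopes$species <- sp
    r$slopes$response <- response
    fits[[sp]] <- r$fit
    attr(fits[[sp]], "fallback") <- r$fallback
    slopes[[sp]] <- r$slopes
  }
  out <- do.call(rbind, slopes)
  rownames(out) <- NULL
  structure(list(type = "temperature", unit = "days/degree C",
                 response = response,
                 slopes = out[, c("species", "class", "response", "slope",
                                  "se", "t", "p")],
                 fits = fits),
            class = "hib_trend")
}

#' Project a yearly trend over a study span
#'
#' Total change implied by a linear per-year slope over a span of years,
#' e.g. a duration trend of 1.81 days/year over 13 years amounts to 23.53
#' days.
#'
#' @param slope_days_per_year trend in days/year.
#' @param n_years span in years; must be positive.
#' @return total change in days.
#' @export
project_total_change <- function(slope_days_per_year, n_years) {
  if (any(n_years <= 0)) stop("n_years must be positive", call. = FALSE)
  slope_days_per_year * n_years
}

#' @export
print.hib_trend <- function(x, digits = 3, ...) {
  lab <- if (x$type == "year") "year trend" else "temperature effect"
  cat(sprintf("Hibernation %s model: %s (%s)\n", lab, x$response, x$unit))
  fb <- vapply(x$fits, function(f) isTRUE(attr(f, "fallback")), logical(1))
  if (any(fb)) {
    cat("  [fixed-effects fallback for:",
        paste(names(fb)[fb], collapse = ", "), "]\n")
  }
  s <- x$slopes
  s$slope <- signif(s$slope, digits)
  s$se <- signif(s$se, digits)
  s$t <- signif(s$t, digits)
  s$p <- signif(s$p, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hib_trend <- function(object, ...) object$slopes

#' @export
summary.hib_trend <- function(object, ...) {
  print(object)
  for (sp in names(object$fits)) {
    cat("\n--- ", sp, " ---\n", sep = "")
    print(summary(object$fits[[sp]]), correlation = FALSE)
  }
  invisible(object)
}
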