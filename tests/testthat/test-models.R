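const_weather <- function(temp = 5, years = 2017:2019) {
  cfg <- sim_config(seed = 1, years = years,
                    weather = list(mean_c = temp, amplitude_c = 0,
                                   warming_c_per_year = 0, noise_sd_c = 0,
                                   annual_anomaly_sd_c = 0))
  simulate_weather(cfg)
}

test_that("window medians match direct recomputation", {
  w <- const_weather(5)
  expect_equal(median_window_temperature(w, c(8, 9), 2018), 5.0)

  # alternating hours 0/10 give a median of 5
  w2 <- w
  w2$temp_c <- rep(c(0, 10), length.out = nrow(w2))
  expect_equal(median_window_temperature(w2, c(8, 9), 2018), 5.0)

  # sinusoidal series against a brute-force median over enumerated hours
  w3 <- w
  w3$temp_c <- 10 + 8 * sin(seq_len(nrow(w3)) / 500)
  mo <- as.integer(format(w3$timestamp, "%m"))
  yr <- as.integer(format(w3$timestamp, "%Y"))
  # Feb-Mar of bat year 2018 lie in calendar 2019
  want <- median(w3$temp_c[(mo == 2 | mo == 3) & yr == 2019])
  expect_equal(median_window_temperature(w3, c(2, 3), 2018), want)
})

test_that("windows without samples or non-consecutive months error", {
  w <- const_weather(5, years = 2018)
  expect_error(median_window_temperature(w, c(8, 10), 2018), "consecutive")
  expect_error(median_window_temperature(w, c(8, 9), 1990), "no weather")
})

test_that("collinearity of identical summaries is 1 and flags constants", {
  cfg <- sim_config(seed = 2, years = 2014:2019,
                    weather = list(mean_c = 9, amplitude_c = 7,
                                   warming_c_per_year = 0, noise_sd_c = 0.5,
                                   annual_anomaly_sd_c = 1))
  w <- simulate_weather(cfg)
  got <- temperature_collinearity(w, 2014:2019)
  expect_equal(nrow(got), 4)
  # median and extremes of the same yearly anomalies co-vary positively
  expect_true(all(got$r_median_max > 0))
  expect_true(all(got$r_median_min > 0))

  cw <- const_weather(5, 2015:2019)
  expect_warning(
    expect_warning(temperature_collinearity(cw, 2015:2019,
                                            default_temp_windows()[1, ]),
                   "constant"),
    "constant")
  flat <- suppressWarnings(temperature_collinearity(cw, 2015:2019))
  expect_true(all(is.na(flat$r_median_max)))
  expect_error(temperature_collinearity(w, 2014:2015), "at least 3")
})

noise_free_phen <- function(seed = 51, entry_trend = -2.14, years = 2010:2022) {
  cfg <- clean_config(seed = seed, n = 10, years = years,
                      class_effects = flat_effects(entry_trend = entry_trend,
                                                   end_trend = 0.5),
                      individual_sd = 0, residual_sd = 0,
                      weather = flat_weather)
  run_pipeline(cfg)$phen
}

test_that("year-trend fits recover a noise-free configured slope exactly", {
  phen <- noise_free_phen()
  suppressWarnings(fit <- fit_year_trend(phen, "start"))
  sl <- coef(fit)
  for (cl in sexage_classes()) {
    got <- sl$slope[sl$species == "daubentonii" & sl$class == cl]
    # on noise-free data every bat of a class sits on the same (day-rounded)
    # line, so the marginal class slope must equal the per-class OLS slope of
    # the truth exactly; that slope is the configured trend up to rounding of
    # schedules to whole days
    sub <- phen[phen$species == "daubentonii" & phen$class == cl, ]
    want <- unname(coef(lm(start_day_index ~ I(bat_year - 2010),
                           data = sub))[2])
    expect_equal(got, want, tolerance = 1e-6)
    expect_equal(got, -2.14, tolerance = 0.12)
  }
})

test_that("the overall slope is the unweighted mean of the class slopes", {
  phen <- noise_free_phen()
  suppressWarnings(fit <- fit_year_trend(phen, "start"))
  sl <- coef(fit)
  for (sp in unique(sl$species)) {
    cls <- sl$slope[sl$species == sp & sl$class != "overall"]
    expect_equal(sl$slope[sl$species == sp & sl$class == "overall"],
                 mean(cls))
  }
  # the published-style arithmetic: four class slopes averaging to -1.115
  expect_equal(mean(c(-0.97, -2.14, -0.70, -0.65)), -1.115)
})

test_that("stronger configured trends give stronger fitted slopes", {
  mags <- c(-0.5, -1.5, -3)
  got <- vapply(mags, function(tr) {
    phen <- noise_free_phen(seed = 57, entry_trend = tr, years = 2014:2020)
    suppressWarnings(fit <- fit_year_trend(phen, "start"))
    sl <- coef(fit)
    mean(abs(sl$slope[sl$class == "overall"]))
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("fits are invariant to row order and class factor order", {
  r <- run_pipeline(clean_config(seed = 52, n = 12, years = 2015:2019))
  phen <- r$phen
  # duration cancels the shared individual intercept, so the mixed fit is
  # legitimately singular here and drops to the documented fallback
  f1 <- suppressWarnings(fit_year_trend(phen, "duration"))
  f2 <- suppressWarnings(fit_year_trend(phen[sample(nrow(phen)), ], "duration"))
  expect_equal(coef(f1)$slope, coef(f2)$slope, tolerance = 1e-8)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  f3 <- suppressWarnings(fit_year_trend(phen, "duration"))
  expect_equal(coef(f1)$slope, coef(f3)$slope, tolerance = 1e-6)
})

test_that("marginal slopes agree with emmeans trend contrasts", {
  skip_if_not_installed("emmeans")
  r <- run_pipeline(clean_config(seed = 53, n = 12, years = 2015:2019))
  fit <- fit_year_trend(r$phen, "start")
  sl <- coef(fit)
  for (sp in names(fit$fits)) {
    em <- emmeans::emtrends(fit$fits[[sp]], "class", var = "year_c",
                            lmer.df = "asymptotic")
    em <- as.data.frame(em)
    want <- em$year_c.trend[match(sl$class[sl$species == sp &
                                             sl$class != "overall"],
                                  as.character(em$class))]
    expect_equal(sl$slope[sl$species == sp & sl$class != "overall"], want,
                 tolerance = 1e-6)
  }
})

test_that("temperature-model slopes are invariant to uniform temperature shifts", {
  cfg <- clean_config(seed = 54, n = 12, years = 2014:2019,
                      weather = list(mean_c = 9, amplitude_c = 7,
                                     warming_c_per_year = 0,
                                     noise_sd_c = 1, annual_anomaly_sd_c = 1))
  r <- run_pipeline(cfg)
  w <- simulate_weather(cfg)
  f1 <- suppressWarnings(fit_temperature_model(r$phen, w, "start"))
  w2 <- w
  w2$temp_c <- w2$temp_c + 3
  f2 <- suppressWarnings(fit_temperature_model(r$phen, w2, "start"))
  expect_equal(coef(f1)$slope, coef(f2)$slope, tolerance = 1e-6)
})

test_that("temperature models refuse to fit on fewer than 3 distinct temperatures", {
  cfg <- clean_config(seed = 55, n = 8, years = 2017:2019,
                      weather = flat_weather)
  r <- run_pipeline(cfg)
  w <- simulate_weather(cfg)
  expect_error(fit_temperature_model(r$phen, w, "start"), "distinct")
})

test_that("trend projections multiply out study-period totals", {
  expect_equal(project_total_change(1.81, 13), 23.53)
  expect_equal(project_total_change(-1.87, 13), -24.31)
  expect_equal(project_total_change(0, 13), 0)
  expect_error(project_total_change(1, 0), "positive")
})

test_that("hib_trend objects print and expose coefficients", {
  r <- run_pipeline(clean_config(seed = 56, n = 8, years = 2017:2019))
  fit <- fit_year_trend(r$phen, "start")
  expect_s3_class(fit, "hib_trend")
  out <- capture.output(print(fit))
  expect_true(any(grepl("days/year", out)))
  expect_named(coef(fit), c("species", "class", "response", "slope", "se",
                            "t", "p"))
})
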