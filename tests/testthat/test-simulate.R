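test_that("degenerate weather settings give a constant series", {
  cfg <- sim_config(seed = 1, years = 2018:2019, weather = flat_weather)
  w <- simulate_weather(cfg)
  expect_true(all(w$temp_c == 8))
  expect_equal(as.numeric(diff(utils::head(w$timestamp, 3)), units = "hours"),
               c(1, 1))
  # one sample per hour over both bat years
  expect_equal(nrow(w), length(seq(w$timestamp[1], w$timestamp[nrow(w)],
                                   by = 3600)))
})

test_that("warming trend appears in annual means at the configured rate", {
  cfg <- sim_config(seed = 1, years = 2015:2020,
                    weather = list(mean_c = 8, amplitude_c = 0,
                                   warming_c_per_year = 0.1, noise_sd_c = 0,
                                   annual_anomaly_sd_c = 0))
  w <- simulate_weather(cfg)
  by <- bat_year(bat_day(w$timestamp))
  means <- tapply(w$temp_c, by, mean)
  means <- means[as.character(2015:2020)]
  k <- 0:5
  expect_equal(as.numeric(means - means[1]), 0.1 * k, tolerance = 0.01)
})

test_that("identical configs reproduce byte-identical datasets", {
  cfg <- sim_config(seed = 99, years = 2018:2019,
                    n_new_tags_per_year_per_species = 10)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$weather, d2$weather)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$captures, d2$captures)
  expect_identical(d1$detections, d2$detections)
})

test_that("with all noise and trends off every entry equals its class baseline", {
  cfg <- clean_config(seed = 3, n = 10, class_effects = flat_effects(),
                      individual_sd = 0, residual_sd = 0,
                      weather = flat_weather)
  d <- simulate_dataset(cfg)
  ce <- default_class_effects()
  key <- match(paste(d$truth$species, d$truth$class),
               paste(ce$species, ce$class))
  expect_equal(day_index(d$truth$true_entry_date, d$truth$bat_year),
               as.integer(ce$baseline_entry[key]))
  expect_equal(day_index(d$truth$true_exit_date, d$truth$bat_year),
               as.integer(ce$baseline_end[key]))
})

test_that("a configured entry trend advances entry dates by exactly the trend", {
  tr <- -2.14
  cfg <- clean_config(seed = 4, n = 8, years = 2015:2020,
                      class_effects = flat_effects(entry_trend = tr),
                      individual_sd = 0, residual_sd = 0,
                      weather = flat_weather)
  d <- simulate_dataset(cfg)
  idx <- day_index(d$truth$true_entry_date, d$truth$bat_year)
  ce <- default_class_effects()
  key <- match(paste(d$truth$species, d$truth$class),
               paste(ce$species, ce$class))
  dy <- d$truth$bat_year - 2015
  expect_equal(idx, floor(ce$baseline_entry[key] + tr * dy + 0.5))
  # least-squares slope of true entry day on year recovers the trend for a
  # cohort whose class never changes (adults of one species); the closed-form
  # expectation is the regression of the day-rounded schedule on year
  ad <- d$truth[d$truth$species == "daubentonii" & d$truth$class == "adult M", ]
  ols <- coef(lm(day_index(true_entry_date, bat_year) ~ bat_year, data = ad))
  base <- ce$baseline_entry[ce$species == "daubentonii" & ce$class == "adult M"]
  dy <- ad$bat_year - 2015  # records per year are unbalanced (cohorts stack)
  want <- coef(lm(floor(base + tr * dy + 0.5) ~ dy))[2]
  expect_equal(unname(ols[2]), unname(want), tolerance = 1e-8)
  expect_equal(unname(ols[2]), tr, tolerance = 0.25)
})

test_that("juveniles are promoted to adults after their first bat year", {
  cfg <- clean_config(seed = 5, n = 30, years = 2016:2019,
                      juvenile_fraction = 1)
  d <- simulate_dataset(cfg)
  tag_year <- as.integer(sub(".*-(\\d{4})-.*", "\\1", d$truth$tag_id))
  expect_true(all(d$truth$age[d$truth$bat_year == tag_year] == "juvenile"))
  expect_true(all(d$truth$age[d$truth$bat_year > tag_year] == "adult"))
  expect_true(all(d$captures$age_at_tagging == "juvenile"))
})

test_that("clean rendering produces four hits per individual-year", {
  cfg <- clean_config(seed = 6, n = 12)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d$detections), 4 * nrow(d$truth))
  expect_setequal(unique(d$detections$reader), c("inner", "outer"))
})

test_that("outage windows delete every hit inside them", {
  out <- data.frame(
    start = as.POSIXct("2018-11-01 00:00:00", tz = "UTC"),
    end = as.POSIXct("2018-11-30 23:59:59", tz = "UTC")
  )
  cfg <- clean_config(seed = 7, n = 20, years = 2018:2019, outages = out)
  d <- simulate_dataset(cfg)
  mo <- format(d$detections$timestamp, "%Y-%m")
  expect_false(any(mo == "2018-11"))
})

test_that("per-hit retention is binomial at the configured p_detect", {
  p <- 0.9
  cfg <- sim_config(seed = 8, years = 2016:2019,
                    n_new_tags_per_year_per_species = 60,
                    swarming_visits_mean = 0, winter_exit_prob = 0,
                    annual_survival = 1, p_detect = p)
  d <- simulate_dataset(cfg)
  n_total <- 4 * nrow(d$truth)
  frac <- nrow(d$detections) / n_total
  half_width <- qnorm(0.995) * sqrt(p * (1 - p) / n_total)
  expect_lt(abs(frac - p), half_width)
})

test_that("configuration is validated", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, years = integer()), "non-empty")
  expect_error(sim_config(seed = 1, years = c(2012, 2011)),
               "strictly increasing")
  expect_error(sim_config(seed = 1, p_detect = 1.2), "p_detect")
  ce <- default_class_effects()
  ce$baseline_entry[1] <- ce$baseline_end[1] + 1
  expect_error(sim_config(seed = 1, class_effects = ce), "precede")
})
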