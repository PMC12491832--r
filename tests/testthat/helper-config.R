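# a small, fully clean configuration: perfect detection, no swarming, no
# mid-winter arousals, no outages, everyone survives
clean_config <- function(seed, years = 2017:2020, n = 15, ...) {
  sim_config(seed = seed, years = years,
             n_new_tags_per_year_per_species = n,
             swarming_visits_mean = 0, winter_exit_prob = 0,
             p_detect = 1, annual_survival = 1, ...)
}

# degenerate weather: every hourly sample identical
flat_weather <- list(mean_c = 8, amplitude_c = 0, warming_c_per_year = 0,
                     noise_sd_c = 0, annual_anomaly_sd_c = 0)

# class_effects with every trend, temperature effect and both sds off
flat_effects <- function(entry_trend = 0, end_trend = 0,
                         temp_effect_entry = 0) {
  ce <- default_class_effects()
  ce$entry_trend <- entry_trend
  ce$end_trend <- end_trend
  ce$temp_effect_entry <- temp_effect_entry
  ce$temp_effect_end <- 0
  ce
}

run_pipeline <- function(cfg, mode = "dual") {
  d <- simulate_dataset(cfg)
  passes <- build_passes(d$detections)
  phen <- compile_phenology(passes, d$captures, mode = mode)
  list(data = d, passes = passes, phen = phen)
}
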