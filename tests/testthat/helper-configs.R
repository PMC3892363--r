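# Shared fixture configurations. All data are generated in code at test
# time; sizes are kept small except where an assertion is about ensemble
# behaviour.

# short default-world run: 4 collars, 11 days spanning sowing/germination
quick_cfg <- function(...) {
  args <- utils::modifyList(list(end_date = "2006-11-10", n_collars = 4),
                            list(...))
  do.call(sim_config, args)
}

# soil-only world with good temperature leverage for Q10 recovery
q10_recovery_cfg <- function(seed = 1) {
  sim_config(start_date = "2006-09-15", end_date = "2006-10-12",
             sowing_date = "2006-10-12", germination_lag_days = 30,
             tmean_c = 12, tamp_c = 6, temp_sigma = 2, rng_seed = seed)
}

# plant-dominated world (no heterotrophic respiration, established canopy)
# isolating the component the suppression multiplier acts on
suppression_recovery_cfg <- function(seed = 11, suppression = 0.8) {
  sim_config(start_date = "2006-12-01", end_date = "2006-12-18",
             sowing_date = "2006-12-01", germination_lag_days = 0,
             growth_rate = 2, growth_midpoint_days = -5, rh0 = 0,
             suppression_s = suppression, rng_seed = seed)
}

# established-canopy world with lid attenuation, for correction tests
uptake_cfg <- function(seed = 3, n_collars = 6, transmission = 0.66) {
  sim_config(start_date = "2006-12-20", end_date = "2007-01-12",
             sowing_date = "2006-12-20", germination_lag_days = 0,
             growth_rate = 2, growth_midpoint_days = -5,
             par_transmission = transmission, n_collars = n_collars,
             rng_seed = seed)
}

# opaque flux records joined to their 5 cm soil temperature
opaque_with_t5 <- function(cfg) {
  env <- generate_environment(cfg)
  traces <- synthesize_traces(cfg, env = env)
  fx <- compute_fluxes(traces, collar_metadata(cfg))
  op <- fx[fx$chamber_type == "opaque" & !is.na(fx$flux), ]
  hour <- as.POSIXct(trunc(op$timestamp, "hours"))
  op$t_soil5_c <- env$t_soil5_c[match(hour, env$timestamp)]
  op
}
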