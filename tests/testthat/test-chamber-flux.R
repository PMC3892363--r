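test_that("an exact line is fitted exactly over the half-open window", {
  t <- 0:139
  tr <- data.frame(t_s = t, co2_ppm = 400 + 0.05 * t)
  s <- fit_trace_slope(tr, deadband_s = 20, window_s = 90)
  expect_equal(s$slope_ppm_s, 0.05, tolerance = 1e-13)
  expect_equal(s$r2, 1)
  expect_equal(s$n, 90)  # [20, 110) at 1 Hz

  flat <- data.frame(t_s = t, co2_ppm = rep(400, length(t)))
  sf <- fit_trace_slope(flat, deadband_s = 20, window_s = 90)
  expect_equal(sf$slope_ppm_s, 0)
})

test_that("slope, SE and r2 match an independent OLS oracle", {
  set.seed(101)
  for (i in 1:100) {
    t <- 0:139
    y <- 400 + runif(1, -0.5, 0.5) * t + rnorm(140, 0, 0.3)
    s <- fit_trace_slope(data.frame(t_s = t, co2_ppm = y),
                         deadband_s = 20, window_s = 90)
    keep <- t >= 20 & t < 110
    o <- oracle_ols(t[keep], y[keep])
    expect_lt(rel_err(s$slope_ppm_s, o$slope), 1e-10)
    expect_lt(rel_err(s$slope_se, o$slope_se), 1e-10)
    expect_lt(rel_err(s$r2, o$r2), 1e-10)
  }
})

test_that("insufficient samples yield an explicit failure, never zero", {
  tr <- data.frame(t_s = 0:5, co2_ppm = 400 + 0.05 * (0:5))
  s <- fit_trace_slope(tr, deadband_s = 0, window_s = 90)
  expect_false(s$ok)
  expect_true(is.na(s$slope_ppm_s))
})

test_that("default dead bands follow chamber type", {
  expect_equal(default_deadband("opaque")$deadband_s, 50)
  expect_equal(default_deadband("transparent")$deadband_s, 20)
  expect_equal(default_deadband("opaque")$window_s, 90)
  expect_equal(default_deadband("transparent")$window_s, 90)
  expect_error(default_deadband("mirrored"), "unknown chamber type")
})

test_that("the ideal-gas conversion gives the worked value and scales right", {
  expect_equal(concentration_slope_to_flux(0.05, 0.00482, 0.0314, 283.15,
                                           101325),
               0.05 * 101325 * 0.00482 / (8.314 * 283.15 * 0.0314))
  expect_equal(round(concentration_slope_to_flux(0.05, 0.00482, 0.0314,
                                                 283.15, 101325), 3), 0.330)
  expect_equal(concentration_slope_to_flux(0, 0.01, 0.03, 280), 0)
  expect_equal(concentration_slope_to_flux(0.05, 2 * 0.00482, 0.0314, 283.15),
               2 * concentration_slope_to_flux(0.05, 0.00482, 0.0314, 283.15))
  expect_error(concentration_slope_to_flux(NaN, 1, 1, 280), "non-finite")
})

test_that("QC flags match an independent recount on a simulated run", {
  cfg <- quick_cfg(rng_seed = 9)
  env <- generate_environment(cfg)
  traces <- synthesize_traces(cfg, env = env)
  fx <- qc_filter(compute_fluxes(traces, collar_metadata(cfg)), env)
  surviving <- sum(fx$chamber_type == "transparent" & qc_pass(fx))
  # brute-force recount with the same thresholds
  hour <- as.POSIXct(trunc(fx$timestamp, "hours"))
  rain <- env$rain[match(hour, env$timestamp)]
  manual <- fx$chamber_type == "transparent" & fx$par_out >= 5 & !rain &
    !(fx$r2 < 0.75 & abs(fx$slope_ppm_s) > 0.03) & !is.na(fx$flux)
  expect_equal(surviving, sum(manual))
  expect_true(all(grepl("night", fx$qc_flags[fx$par_out == 0])))
})

test_that("clean daytime records carry no flags", {
  rec <- tibble::tibble(flux = -2, slope_ppm_s = -0.2, r2 = 0.99,
                        par_out = 500, timestamp = Sys.time(), qc_flags = "")
  expect_equal(qc_filter(rec)$qc_flags, "")
})

test_that("cycle pairing handles pairs, singletons and ambiguity", {
  ts <- as.POSIXct("2006-12-01 10:00:00", tz = "UTC")
  rec <- tibble::tibble(
    closure_id = c("a", "b"), collar_id = 1L,
    chamber_type = c("transparent", "opaque"),
    timestamp = c(ts, ts + 120), flux = c(-3, 2)
  )
  p <- pair_cycle(rec)
  expect_equal(nrow(p), 1)
  expect_true(p$paired)
  expect_equal(p$nee, -3)
  expect_equal(p$reco, 2)

  solo <- rec[2, ]
  ps <- pair_cycle(solo)
  expect_false(ps$paired)
  expect_true(is.na(ps$nee))
  expect_equal(ps$reco, 2)

  dup <- rbind(rec, tibble::tibble(closure_id = "c", collar_id = 1L,
                                   chamber_type = "opaque",
                                   timestamp = ts + 300, flux = 2.5))
  expect_error(pair_cycle(dup), "b.*c|ambiguous")
})

test_that("pair counts on a season match the closure schedule", {
  cfg <- quick_cfg(rng_seed = 4)
  traces <- synthesize_traces(cfg)
  fx <- compute_fluxes(traces, collar_metadata(cfg))
  p <- pair_cycle(fx)
  cl <- attr(traces, "closures")
  both <- cl |>
    dplyr::mutate(hour = as.POSIXct(trunc(timestamp, "hours"))) |>
    dplyr::count(collar_id, hour) |>
    dplyr::summarise(n2 = sum(n == 2))
  expect_equal(sum(p$paired), both$n2)
  expect_equal(nrow(p), nrow(cl |>
    dplyr::mutate(hour = as.POSIXct(trunc(timestamp, "hours"))) |>
    dplyr::distinct(collar_id, hour)))
})

test_that("round trip recovers fluxes: exact noise-free, within SE noisy", {
  cl <- attr(synthesize_traces(quick_cfg(rng_seed = 6)), "closures")
  cfg <- quick_cfg(rng_seed = 6)
  traces <- synthesize_traces(cfg)
  fx <- compute_fluxes(traces, collar_metadata(cfg))
  j <- dplyr::inner_join(fx, cl[, c("closure_id", "true_flux")],
                         by = "closure_id")
  flux_se <- j$slope_se * j$flux / j$slope_ppm_s
  within3 <- abs(j$flux - j$true_flux) <= 3 * abs(flux_se)
  expect_gt(mean(within3), 0.99)
})

test_that("sign convention: respiration releases, photosynthesis takes up", {
  cfg <- noise_free(sim_config())
  resp <- synthesize_trace(0.8, cfg, "opaque", t_air_c = 5)
  up <- synthesize_trace(-4, cfg, "transparent", par_out = 600, t_air_c = 5)
  s1 <- fit_trace_slope(resp)
  s2 <- fit_trace_slope(up)
  expect_gt(concentration_slope_to_flux(s1$slope_ppm_s, resp$volume_m3,
                                        resp$area_m2, 278.15), 0)
  expect_lt(concentration_slope_to_flux(s2$slope_ppm_s, up$volume_m3,
                                        up$area_m2, 278.15), 0)
})
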