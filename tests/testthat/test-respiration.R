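test_that("soil-only respiration selects the 5 cm soil temperature", {
  cfg <- quick_cfg(rng_seed = 12)
  env <- generate_environment(cfg)
  truth <- generate_true_fluxes(cfg, env)
  pre <- truth[as.Date(truth$timestamp, tz = "UTC") <= cfg$sowing_date, ]
  rec <- tibble::tibble(timestamp = pre$timestamp, flux = pre$rhet)
  sel <- select_temperature_driver(rec, env)
  expect_equal(sel$best, "t_soil5_c")
  expect_equal(max(sel$table$correlation), 1, tolerance = 1e-9)
})

test_that("driver ties resolve to the first candidate in fixed order", {
  cfg <- quick_cfg()
  env <- generate_environment(cfg)
  env$t_surf_c <- env$t_air_c
  env$t_soil2_c <- env$t_air_c
  env$t_soil5_c <- env$t_air_c
  rec <- tibble::tibble(timestamp = env$timestamp,
                        flux = 0.1 * exp(0.09 * env$t_air_c))
  expect_equal(select_temperature_driver(rec, env)$best, "t_air_c")
})

test_that("driver correlations equal the brute-force Pearson oracle", {
  cfg <- quick_cfg(rng_seed = 17)
  env <- generate_environment(cfg)
  set.seed(99)
  flux <- 0.12 * exp(0.08 * env$t_air_c) * exp(rnorm(nrow(env), 0, 0.2))
  rec <- tibble::tibble(timestamp = env$timestamp, flux = flux)
  sel <- select_temperature_driver(rec, env)
  for (i in seq_len(nrow(sel$table))) {
    v <- sel$table$candidate[i]
    expect_lt(rel_err(sel$table$correlation[i],
                      oracle_pearson(log(flux), env[[v]])), 1e-12)
  }
})

test_that("the printed seedling-stage regression refits to Q10 = 2.46", {
  t <- seq(0, 15, by = 0.1)
  f <- fit_q10(0.17 * exp(0.09 * t), t)
  expect_equal(f$b, 0.09, tolerance = 1e-12)
  expect_equal(round(f$q10, 2), 2.46)
  expect_equal(f$q10, exp(10 * f$b))  # identity holds exactly
  expect_equal(f$a, 0.17, tolerance = 1e-10)
  expect_equal(f$r2, 1)
})

test_that("Q10 limiting cases behave", {
  t <- seq(0, 15, by = 0.5)
  expect_equal(fit_q10(rep(0.3, length(t)), t)$q10, 1, tolerance = 1e-12)
  expect_equal(fit_q10(0.2 * 2^(t / 10), t)$q10, 2, tolerance = 1e-12)
})

test_that("Q10 is invariant to a temperature offset; only `a` changes", {
  set.seed(5)
  t <- runif(80, 0, 15)
  r <- 0.2 * exp(0.1 * t) * exp(rnorm(80, 0, 0.1))
  f1 <- fit_q10(r, t)
  f2 <- fit_q10(r, t + 7.3)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
  expect_equal(f1$q10, f2$q10, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$a, f2$a)))
})

test_that("refitting data generated from a fit reproduces it exactly", {
  set.seed(8)
  t <- runif(60, 2, 14)
  f1 <- fit_q10(0.15 * exp(0.085 * t) * exp(rnorm(60, 0, 0.15)), t)
  f2 <- fit_q10(f1$a * exp(f1$b * t), t)
  expect_lt(abs(f2$b - f1$b), 1e-9)
})

test_that("non-positive fluxes are excluded and counted; too few refuse", {
  t <- seq(0, 15, by = 1)
  r <- 0.2 * exp(0.09 * t)
  r[3] <- -0.01
  f <- fit_q10(r, t)
  expect_equal(f$n_excluded, 1L)
  expect_equal(f$n, length(t) - 1L)
  expect_error(fit_q10(c(1, 2, -1, -2), c(1, 2, 3, 4)), "positive")
})

test_that("stage segmentation follows the printed boundary dates", {
  w <- stage_windows(sim_config())
  rec <- tibble::tibble(timestamp = as.POSIXct(
    c("2006-11-14 00:30:00", "2006-10-31 10:00:00", "2006-11-13 23:00:00",
      "2006-11-28 00:00:00", "2007-01-23 12:00:00"), tz = "UTC"))
  out <- segment_stages(rec, w)
  expect_equal(out$stage, c("S3", "S1", "S2", "S4", "S4"))
  bad <- tibble::tibble(timestamp = as.POSIXct("2007-06-01", tz = "UTC"))
  expect_error(segment_stages(bad, w), "outside")
})

test_that("stage record counts match a brute-force date comparison", {
  cfg <- sim_config(end_date = "2006-12-05")
  env <- generate_environment(cfg)
  rec <- tibble::tibble(timestamp = env$timestamp, flux = 1)
  out <- segment_stages(rec, stage_windows(cfg))
  d <- as.Date(rec$timestamp, tz = "UTC")
  expect_equal(sum(out$stage == "S2"),
               sum(d >= as.Date("2006-11-04") & d <= as.Date("2006-11-13")))
  expect_equal(sum(out$stage == "S1"),
               sum(d <= as.Date("2006-11-03")))
})

test_that("daytime suppression is recovered and null when absent", {
  cfg <- suppression_recovery_cfg()
  op <- opaque_with_t5(cfg)
  expect_gte(nrow(op), 5000)
  est <- day_night_suppression(op$flux, op$temperature_c, op$par_out > 5)
  expect_lt(abs(est$ratio - 0.8), 0.02)

  cfg1 <- suppression_recovery_cfg(seed = 12, suppression = 1)
  op1 <- opaque_with_t5(cfg1)
  est1 <- day_night_suppression(op1$flux, op1$temperature_c, op1$par_out > 5)
  expect_lt(abs(est1$ratio - 1), 3 * est1$se_ratio)
  expect_gt(est1$p_value, 0.01)
})

test_that("the day coefficient equals the two-covariate OLS oracle", {
  set.seed(44)
  t <- runif(400, 0, 12)
  day <- runif(400) < 0.4
  r <- 0.3 * exp(0.08 * t) * ifelse(day, 0.8, 1) * exp(rnorm(400, 0, 0.1))
  est <- day_night_suppression(r, t, day)
  expect_lt(rel_err(est$d, oracle_day_coef(log(r), t, day)), 1e-10)
  expect_error(day_night_suppression(r[day], t[day], day[day]), "both day")
})

test_that("GPP partitioning follows the sign convention and clips", {
  p <- tibble::tibble(collar_id = 1, hour = Sys.time() + 1:3 * 3600,
                      nee = c(-5, 2, 1), reco = c(3, 2, 0.5), paired = TRUE)
  out <- partition_gpp(p)
  expect_equal(out$gpp, c(8, 0, 0))
  expect_equal(attr(out, "n_clipped"), 1L)
  p$paired[2] <- FALSE
  expect_error(partition_gpp(p), "unpaired")
  expect_equal(nrow(partition_gpp(p, drop_unpaired = TRUE)), 2)
})

test_that("partitioned GPP recovers the simulated truth", {
  # measurement-artifact-free lid so measured GPP targets the ambient truth
  cfg <- uptake_cfg(seed = 2, n_collars = 4, transmission = 1)
  env <- generate_environment(cfg)
  truth <- generate_true_fluxes(cfg, env)
  traces <- synthesize_traces(cfg, truth = truth, env = env)
  fx <- compute_fluxes(traces, collar_metadata(cfg))
  gpp <- partition_gpp(pair_cycle(fx), drop_unpaired = TRUE)
  j <- dplyr::inner_join(gpp, truth[, c("collar_id", "timestamp", "gpp")],
                         by = c("collar_id", "hour" = "timestamp"),
                         suffix = c("_est", "_true"))
  day <- j$gpp_true > 0
  rmse <- sqrt(mean((j$gpp_est[day] - j$gpp_true[day])^2))
  se_rec <- median(fx$slope_se / abs(fx$slope_ppm_s) * abs(fx$flux),
                   na.rm = TRUE)
  expect_lt(rmse, 2 * sqrt(2) * se_rec)
  night <- !day
  expect_lt(mean(j$gpp_est[night]), 0.05)  # nighttime GPP ~ 0
})
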