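test_that("exact transmission is recovered from exact pairs", {
  po <- c(100, 500, 1000, seq(50, 800, by = 50))
  m <- fit_attenuation(po, 0.66 * po)
  expect_equal(m$tau, 0.66, tolerance = 1e-12)
  expect_equal(m$attenuation, 0.34, tolerance = 1e-12)
  ident <- fit_attenuation(po, po)
  expect_equal(ident$tau, 1)
  expect_equal(ident$attenuation, 0)
})

test_that("through-origin slope matches the regression oracle on noisy pairs", {
  set.seed(21)
  for (i in 1:20) {
    x <- runif(60, 5, 900)
    y <- 0.66 * x + rnorm(60, 0, 15)
    m <- fit_attenuation(x, y)
    expect_lt(rel_err(m$tau, oracle_through_origin(x, y)), 1e-12)
  }
})

test_that("attenuation fit guards its preconditions", {
  expect_error(fit_attenuation(rep(0, 30), rep(0, 30)), "all-zero PAR")
  expect_error(fit_attenuation(c(100, 200), c(66, 132)), "at least")
})

test_that("the printed light response is recovered exactly from exact data", {
  par <- seq(20, 900, by = 10)
  rec <- tibble::tibble(flux = -(0.74 * log(par) + 3.51), par_out = par)
  m <- fit_light_response(rec)
  expect_equal(unname(m$coef["a"]), 0.74, tolerance = 1e-10)
  expect_equal(unname(m$coef["c"]), 3.51, tolerance = 1e-10)
  expect_equal(m$r2, 1)
})

test_that("PAR-independent uptake yields a zero slope", {
  par <- seq(20, 900, by = 10)
  rec <- tibble::tibble(flux = rep(-2.5, length(par)), par_out = par)
  expect_equal(unname(fit_light_response(rec)$coef["a"]), 0,
               tolerance = 1e-12)
})

test_that("light-response coefficients equal the normal-equation oracle", {
  set.seed(33)
  par <- runif(200, 10, 900)
  uptake <- 0.7 * log(par) + 3 + rnorm(200, 0, sqrt(par) / 15)
  m <- fit_light_response(tibble::tibble(flux = -uptake, par_out = par))
  o <- oracle_ols(log(par), uptake)
  expect_lt(rel_err(unname(m$coef["a"]), o$slope), 1e-10)
  expect_lt(rel_err(unname(m$coef["c"]), o$intercept), 1e-10)
})

test_that("too few points refuse to fit", {
  rec <- tibble::tibble(flux = rep(-1, 10), par_out = seq(50, 500, len = 10))
  expect_error(fit_light_response(rec), "at least 20")
})

log_model <- function(a = 0.74, c = 3.51) {
  structure(list(form = "log", coef = c(a = a, c = c),
                 par_range = c(5, 1000)),
            class = "light_response_model")
}

test_that("the log-form offset is the analytic constant", {
  m <- log_model()
  expect_equal(correction_offset(m, 300, 0.66), 0.74 * log(1 / 0.66),
               tolerance = 1e-12)
  grid <- correction_offset(m, seq(10, 650, by = 5), 0.66)
  expect_equal(diff(range(grid)), 0)
  expect_equal(round(grid[1], 3), 0.307)
  expect_equal(correction_offset(m, 400, 1), 0)
  expect_equal(correction_offset(log_model(a = 0), 400, 0.66), 0)
})

test_that("the offset is nonincreasing in transmission and nonnegative", {
  m <- log_model()
  taus <- seq(0.4, 1, by = 0.05)
  deltas <- vapply(taus, function(tt) correction_offset(m, 300, tt),
                   numeric(1))
  expect_true(all(diff(deltas) <= 0))
  expect_true(all(deltas >= 0))
  expect_equal(deltas[length(deltas)], 0)
})

test_that("extrapolation beyond the fitted PAR domain warns but computes", {
  m <- log_model()
  expect_warning(d <- correction_offset(m, 900, 0.66), "extrapolation")
  expect_equal(d, 0.74 * log(1 / 0.66), tolerance = 1e-12)
})

test_that("correction applies only to eligible transparent daytime records", {
  ts <- as.POSIXct("2006-12-01 12:00:00", tz = "UTC")
  rec <- tibble::tibble(
    closure_id = c("t1", "o1", "t2", "t3"),
    collar_id = 1L,
    chamber_type = c("transparent", "opaque", "transparent", "transparent"),
    timestamp = c(ts, ts, ts + 3600, as.POSIXct("2006-11-01 12:00:00",
                                                tz = "UTC")),
    flux = c(-2.0, 1.5, -1.0, -0.5),
    par_in = c(200, 0, NA, 200),
    par_out = c(303, 303, 303, 303),
    qc_flags = ""
  )
  out <- apply_correction(rec, log_model(), tau = 0.66,
                          onset_date = "2006-11-21")
  expect_equal(out$flux_corrected[1], -2.0 - 0.74 * log(1 / 0.66),
               tolerance = 1e-10)
  expect_equal(round(out$flux_corrected[1], 3), -2.307)
  expect_equal(out$flux_corrected[2], 1.5)    # opaque unchanged
  expect_equal(out$flux_corrected[3], -1.0)   # missing PAR: uncorrected
  expect_match(out$qc_flags[3], "missing_par")
  expect_equal(out$flux_corrected[4], -0.5)   # pre-onset unchanged
  rep <- attr(out, "correction_report")
  expect_equal(rep$n_corrected, 1L)
  expect_equal(rep$n_missing_par, 1L)
})

test_that("corrected cumulative NEE never exceeds the uncorrected one", {
  cfg <- uptake_cfg()
  traces <- synthesize_traces(cfg)
  fx <- qc_filter(compute_fluxes(traces, collar_metadata(cfg)),
                  generate_environment(cfg))
  day_t <- fx$chamber_type == "transparent" & qc_pass(fx)
  lr <- fit_light_response(fx[day_t, ])
  out <- apply_correction(fx, lr, 0.66, onset_date = cfg$start_date)
  expect_gt(unname(lr$coef["a"]), 0)
  tot_corr <- sum(out$flux_corrected[out$chamber_type == "transparent"])
  tot_raw <- sum(out$flux[out$chamber_type == "transparent"])
  expect_lte(tot_corr, tot_raw)
})

test_that("simulated transmission is recovered within 0.01 without sensor noise", {
  cfg <- quick_cfg(sensor_sigma_par = 0, rng_seed = 8)
  cl <- attr(synthesize_traces(cfg), "closures")
  day_t <- cl$chamber_type == "transparent" & cl$par_out > 5
  m <- fit_attenuation(cl$par_out[day_t], cl$par_in[day_t])
  expect_lt(abs(m$tau - cfg$par_transmission), 0.01)
})

test_that("the correction shrinks the budget bias against the truth", {
  cfg <- uptake_cfg(seed = 5)
  env <- generate_environment(cfg)
  truth <- generate_true_fluxes(cfg, env)
  traces <- synthesize_traces(cfg, truth = truth, env = env)
  doc <- generate_doc_events(cfg, env)
  inv <- generate_stock_inventory(cfg, truth, doc)
  fx <- qc_filter(compute_fluxes(traces, collar_metadata(cfg)), env)
  day_t <- fx$chamber_type == "transparent" & qc_pass(fx)
  lr <- fit_light_response(fx[day_t, ])
  att <- fit_attenuation(fx$par_out[day_t], fx$par_in[day_t])
  corrected <- apply_correction(fx, lr, att$tau, onset_date = cfg$start_date)

  true_bal <- truth |>
    dplyr::group_by(collar_id) |>
    dplyr::summarise(g = sum(nee) * 3600 * 12.011e-6 * cfg$collar_area)
  bias_of <- function(records) {
    b <- pipeline_budgets(records, doc, inv, cfg)
    mean(b$cum_nee_c - true_bal$g)
  }
  uncorr <- fx
  uncorr$flux_corrected <- uncorr$flux
  expect_lt(abs(bias_of(corrected)), abs(bias_of(uncorr)))
})
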