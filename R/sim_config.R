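#' Configuration for the synthetic mesocosm experiment
#'
#' Builds the full parameter set driving the forward simulator: experiment
#' calendar, chamber/collar geometry, respiration and photosynthesis model
#' parameters, plant growth trajectory, carbon fractions, leaching, and all
#' observation-noise magnitudes. Defaults emulate the study conditions of a
#' winter ryegrass (*Lolium perenne*) mesocosm run in northern England:
#' 12 collars in a 2 (chamber) x 2 (nutrient) design, hourly paired
#' transparent/opaque chamber closures from 31 Oct 2006 to 23 Jan 2007, a
#' transparent lid transmitting 66% of ambient PAR, and daytime suppression
#' of autotrophic dark respiration.
#'
#' @param start_date,end_date Calendar dates bounding the run (inclusive).
#' @param sowing_date Date seeds are sown; transparent (NEE) closures begin
#'   the day after the pre-sowing, respiration-only period ends.
#' @param n_collars Number of mesocosm collars (split evenly over the four
#'   chamber x nutrient treatment combinations).
#' @param collar_area Collar soil surface area, m^2.
#' @param chamber_volume Chamber + analyser + tubing headspace volume, m^3,
#'   before per-collar rim offsets.
#' @param stage_boundaries Named Date vector with the start dates of the four
#'   developmental stages `S1` (pre-sowing, soil only), `S2` (germination),
#'   `S3` (seedling), `S4` (plant); each stage runs to the day before the
#'   next stage (S4 to `end_date`). `NULL` (default) uses the study dates
#'   (31 Oct / 4 Nov / 14 Nov / 28 Nov 2006) when the calendar matches, and
#'   equal quarters of the run otherwise.
#' @param par_transmission Fraction of ambient PAR transmitted by the
#'   transparent lid (tau), in (0, 1].
#' @param rh0 Heterotrophic (soil) respiration at the reference temperature,
#'   umol CO2 m^-2 s^-1.
#' @param q10_het,q10_auto Q10 temperature sensitivities (dimensionless, > 0)
#'   of heterotrophic and autotrophic respiration. Heterotrophic respiration
#'   follows soil temperature at 5 cm; autotrophic follows air temperature.
#' @param tref Reference temperature for both Q10 laws, degrees C.
#' @param rauto_coeff Autotrophic respiration per gram shoot dry weight at
#'   `tref`, umol m^-2 s^-1 g^-1.
#' @param lr_coeff_a,lr_coeff_c Logarithmic light-response coefficients:
#'   canopy uptake at full biomass is `a * log(PAR) + c` (umol m^-2 s^-1),
#'   clipped at zero below the curve's zero crossing.
#' @param suppression_s Daytime multiplier on autotrophic dark respiration
#'   in (0, 1]; 1 disables the day/night suppression.
#' @param germination_lag_days Days between sowing and germination.
#' @param growth_rate Logistic growth rate, d^-1.
#' @param growth_midpoint_days Logistic midpoint, days after germination.
#' @param shoot_dw_max,root_dw_max Logistic shoot/root dry-weight asymptotes,
#'   g per collar (realized final mass is below the asymptote when growth has
#'   not saturated by harvest).
#' @param gpp_ref_dw Reference shoot dry weight (g) at which the canopy
#'   achieves the full reference light response; GPP amplitude scales as
#'   `shoot_dw / gpp_ref_dw`.
#' @param biomass_cv Collar-to-collar coefficient of variation of the growth
#'   trajectory (biological replication, not measurement noise).
#' @param seed_mass_g Seed dry mass sown per collar, g.
#' @param soil_mass_g Soil dry mass per collar, g.
#' @param c_fractions Named carbon mass fractions in (0, 1) for `seed`,
#'   `shoot`, `root`, `soil`.
#' @param doc_conc Mean dissolved organic carbon concentration of drainage
#'   water, mg L^-1, and `doc_conc_sd` its per-event standard deviation.
#' @param doc_conc_sd See `doc_conc`.
#' @param doc_collect_threshold_l Accumulated drainage volume (L) that
#'   triggers a collection event once rain stops.
#' @param doc_collection_efficiency Fraction of leached carbon captured by
#'   the drainage bottle; the remainder percolates past the collector and is
#'   debited from the soil pool. At the default 0.5 the flux-side balance
#'   (cumulative NEE + collected DOC) closes exactly against the Eq.-1 stock
#'   inventory (see the methods vignette).
#' @param rain_p01,rain_p11 Hourly rain Markov-chain probabilities
#'   (dry->wet, wet->wet).
#' @param rain_mm_per_h Drainage-effective rainfall per wet hour, mm.
#' @param tmean_c,tamp_c Mean and diurnal amplitude of air temperature, C.
#' @param temp_sigma,temp_rho AR(1) noise sd (C) and autocorrelation of the
#'   temperature series.
#' @param par_max Clear-sky PAR maximum at solar noon, umol m^-2 s^-1.
#' @param sunrise_h,sunset_h Local hours bounding daylight; PAR is exactly 0
#'   outside them.
#' @param cloud_depth Depth of the daily cloudiness reduction in \[0, 1);
#'   daily PAR is scaled by `1 - cloud_depth * Beta(2, 2)`. Treated as a
#'   noise level: 0 gives the exact clear-sky curve.
#' @param sensor_sigma_par PAR sensor noise sd, umol m^-2 s^-1.
#' @param baseline_co2 Mean chamber CO2 at closure start, ppm, with
#'   `baseline_co2_sd` its per-closure spread.
#' @param baseline_co2_sd See `baseline_co2`.
#' @param trace_sigma White noise sd on trace CO2 readings, ppm.
#' @param transient_amp Amplitude of the exponential chamber-mixing
#'   transient, ppm; e-folding time 10 s, rate contribution confined to the
#'   first 20 s of closure.
#' @param drawdown_efold_s E-folding time (s) of the decaying photosynthetic
#'   drawdown seen by opaque chambers closed in daylight; its rate
#'   contribution is confined to the first 50 s.
#' @param inventory_sigma_soil,inventory_sigma_pool Measurement noise sd
#'   (g C) on the soil-change pool and on each other inventory pool.
#' @param trace_length_s Closure trace length, s, sampled at 1 Hz. The
#'   default 140 covers the default opaque fit window (50 s dead band +
#'   90 s calculation period).
#' @param pressure_pa Barometric pressure, Pa.
#' @param night_par PAR threshold (umol m^-2 s^-1) below which an hour is
#'   treated as night.
#' @param rng_seed Integer seed; all collar-level randomness uses per-collar
#'   substreams derived from it, so adding collars does not perturb existing
#'   ones.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(end_date = "2006-11-10", n_collars = 4)
#' cfg$par_transmission
sim_config <- function(start_date = "2006-10-31",
                       end_date = "2007-01-23",
                       sowing_date = "2006-11-03",
                       n_collars = 12,
                       collar_area = 0.0278,
                       chamber_volume = 0.00482,
                       stage_boundaries = NULL,
                       par_transmission = 0.66,
                       rh0 = 0.11,
                       q10_het = 2.45,
                       q10_auto = 2.6,
                       tref = 10,
                       rauto_coeff = 0.15,
                       lr_coeff_a = 0.74,
                       lr_coeff_c = 3.51,
                       suppression_s = 0.8,
                       germination_lag_days = 11,
                       growth_rate = 0.15,
                       growth_midpoint_days = 30,
                       shoot_dw_max = 1.76,
                       root_dw_max = 2.44,
                       gpp_ref_dw = 7.2,
                       biomass_cv = 0.12,
                       seed_mass_g = 3.13,
                       soil_mass_g = 2500,
                       c_fractions = c(seed = 0.415, shoot = 0.405,
                                       root = 0.345, soil = 0.005),
                       doc_conc = 20,
                       doc_conc_sd = 1.5,
                       doc_collect_threshold_l = 0.6,
                       doc_collection_efficiency = 0.5,
                       rain_p01 = 0.03,
                       rain_p11 = 0.70,
                       rain_mm_per_h = 0.85,
                       tmean_c = 5,
                       tamp_c = 3,
                       temp_sigma = 1.2,
                       temp_rho = 0.8,
                       par_max = 650,
                       sunrise_h = 8,
                       sunset_h = 16,
                       cloud_depth = 0.45,
                       sensor_sigma_par = 5,
                       baseline_co2 = 400,
                       baseline_co2_sd = 4,
                       trace_sigma = 0.3,
                       transient_amp = 2,
                       drawdown_efold_s = 15,
                       inventory_sigma_soil = 0.005,
                       inventory_sigma_pool = 0.002,
                       trace_length_s = 140,
                       pressure_pa = 101325,
                       night_par = 5,
                       rng_seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.null(stage_boundaries)) {
    study <- as.Date(c(S1 = "2006-10-31", S2 = "2006-11-04",
                       S3 = "2006-11-14", S4 = "2006-11-28"))
    names(study) <- c("S1", "S2", "S3", "S4")
    stage_boundaries <- if (study[["S1"]] == start_date &&
                            study[["S4"]] <= end_date) {
      study
    } else {
      # equal quarters for non-study calendars
      n <- as.integer(end_date - start_date) + 1L
      q <- start_date + floor((0:3) * n / 4)
      names(q) <- c("S1", "S2", "S3", "S4")
      q
    }
  }
  cfg <- list(
    start_date = start_date,
    end_date = end_date,
    sowing_date = as.Date(sowing_date),
    n_collars = as.integer(n_collars),
    collar_area = collar_area,
    chamber_volume = chamber_volume,
    stage_boundaries = stats::setNames(as.Date(stage_boundaries),
                                       names(stage_boundaries)),
    par_transmission = par_transmission,
    rh0 = rh0,
    q10_het = q10_het,
    q10_auto = q10_auto,
    tref = tref,
    rauto_coeff = rauto_coeff,
    lr_coeff_a = lr_coeff_a,
    lr_coeff_c = lr_coeff_c,
    suppression_s = suppression_s,
    germination_lag_days = germination_lag_days,
    growth_rate = growth_rate,
    growth_midpoint_days = growth_midpoint_days,
    shoot_dw_max = shoot_dw_max,
    root_dw_max = root_dw_max,
    gpp_ref_dw = gpp_ref_dw,
    biomass_cv = biomass_cv,
    seed_mass_g = seed_mass_g,
    soil_mass_g = soil_mass_g,
    c_fractions = c_fractions,
    doc_conc = doc_conc,
    doc_conc_sd = doc_conc_sd,
    doc_collect_threshold_l = doc_collect_threshold_l,
    doc_collection_efficiency = doc_collection_efficiency,
    rain_p01 = rain_p01,
    rain_p11 = rain_p11,
    rain_mm_per_h = rain_mm_per_h,
    tmean_c = tmean_c,
    tamp_c = tamp_c,
    temp_sigma = temp_sigma,
    temp_rho = temp_rho,
    par_max = par_max,
    sunrise_h = sunrise_h,
    sunset_h = sunset_h,
    cloud_depth = cloud_depth,
    sensor_sigma_par = sensor_sigma_par,
    baseline_co2 = baseline_co2,
    baseline_co2_sd = baseline_co2_sd,
    trace_sigma = trace_sigma,
    transient_amp = transient_amp,
    drawdown_efold_s = drawdown_efold_s,
    inventory_sigma_soil = inventory_sigma_soil,
    inventory_sigma_pool = inventory_sigma_pool,
    trace_length_s = trace_length_s,
    pressure_pa = pressure_pa,
    night_par = night_par,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the invariants the simulator relies on (date ordering, contiguous
#' stage windows, parameter ranges) and returns the config invisibly
#' unchanged, or stops with an informative error.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly-validated (returned visibly for chaining).
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$end_date > cfg$start_date) {
    stop("`end_date` must be after `start_date`", call. = FALSE)
  }
  if (cfg$sowing_date < cfg$start_date || cfg$sowing_date > cfg$end_date) {
    stop("`sowing_date` must lie within the run", call. = FALSE)
  }
  sb <- cfg$stage_boundaries
  if (length(sb) != 4L || !identical(names(sb), c("S1", "S2", "S3", "S4"))) {
    stop("`stage_boundaries` must be four dates named S1..S4", call. = FALSE)
  }
  if (any(diff(sb) <= 0)) {
    stop("stage boundaries must be strictly increasing (contiguous, ",
         "non-overlapping stages)", call. = FALSE)
  }
  if (sb[["S1"]] != cfg$start_date || sb[["S4"]] > cfg$end_date) {
    stop("stages must cover the run: S1 starts at `start_date` and S4 ",
         "starts on or before `end_date`", call. = FALSE)
  }
  chk_in <- function(x, lo, hi, nm, lo_open = FALSE, hi_open = FALSE) {
    bad <- !is.finite(x) |
      (if (lo_open) x <= lo else x < lo) |
      (if (hi_open) x >= hi else x > hi)
    if (any(bad)) stop(sprintf("`%s` must be in %s%g, %g%s", nm,
                               if (lo_open) "(" else "[", lo, hi,
                               if (hi_open) ")" else "]"), call. = FALSE)
  }
  chk_in(cfg$par_transmission, 0, 1, "par_transmission", lo_open = TRUE)
  chk_in(cfg$suppression_s, 0, 1, "suppression_s", lo_open = TRUE)
  chk_in(cfg$doc_collection_efficiency, 0, 1, "doc_collection_efficiency",
         lo_open = TRUE)
  chk_in(cfg$cloud_depth, 0, 1, "cloud_depth", hi_open = TRUE)
  if (cfg$q10_het <= 0 || cfg$q10_auto <= 0) {
    stop("Q10 values must be > 0", call. = FALSE)
  }
  cf <- cfg$c_fractions
  if (!all(c("seed", "shoot", "root", "soil") %in% names(cf))) {
    stop("`c_fractions` must name seed, shoot, root and soil", call. = FALSE)
  }
  chk_in(cf, 0, 1, "c_fractions", lo_open = TRUE, hi_open = TRUE)
  pos <- c("n_collars", "collar_area", "chamber_volume", "trace_length_s",
           "pressure_pa", "seed_mass_g", "soil_mass_g", "shoot_dw_max",
           "root_dw_max", "gpp_ref_dw")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  nonneg <- c("rh0", "rauto_coeff", "trace_sigma", "transient_amp",
              "sensor_sigma_par", "temp_sigma", "biomass_cv", "doc_conc",
              "doc_conc_sd", "inventory_sigma_soil", "inventory_sigma_pool",
              "rain_mm_per_h")
  for (nm in nonneg) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    }
  }
  cfg
}

#' Switch off every observation-noise source of a configuration
#'
#' Returns a copy of the configuration with trace noise, sensor noise,
#' temperature noise, cloudiness variability, concentration noise, inventory
#' measurement noise, mixing transients and baseline spread all set to zero.
#' Biological collar-to-collar variation (`biomass_cv`) and rainfall are left
#' untouched: they are properties of the simulated world, not of the
#' instruments observing it.
#'
#' @param cfg A `sim_config`.
#' @param transmission Optionally override `par_transmission` as well; the
#'   lid attenuation is an observation artifact, so measurement-artifact-free
#'   runs typically also set it to 1.
#' @return A modified `sim_config`.
#' @export
noise_free <- function(cfg, transmission = NULL) {
  cfg$trace_sigma <- 0
  cfg$sensor_sigma_par <- 0
  cfg$temp_sigma <- 0
  cfg$cloud_depth <- 0
  cfg$doc_conc_sd <- 0
  cfg$inventory_sigma_soil <- 0
  cfg$inventory_sigma_pool <- 0
  cfg$transient_amp <- 0
  cfg$baseline_co2_sd <- 0
  if (!is.null(transmission)) cfg$par_transmission <- transmission
  validate_sim_config(cfg)
}

#' Per-collar metadata: treatments and chamber geometry
#'
#' Assigns the 2 x 2 chamber/nutrient treatment labels (replicates split
#' evenly) and the per-collar headspace volume. Collar rim heights differ by
#' a few millimetres, so each collar's effective volume carries an individual
#' offset (`chamber_volume + area * rim_height`), drawn deterministically
#' from the configuration seed.
#'
#' @param cfg A `sim_config`.
#' @return A tibble with `collar_id`, `chamber_trt`, `nutrient_trt`,
#'   `treatment`, `volume_m3`, `area_m2`.
#' @export
collar_metadata <- function(cfg) {
  n <- cfg$n_collars
  trt <- expand.grid(chamber_trt = c("+Ch", "-Ch"),
                     nutrient_trt = c("+N", "-N"),
                     stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(trt)), length.out = n)
  # rim height 5-25 mm above soil, fixed per collar
  rim <- with_collar_seed(cfg$rng_seed, 0L, stats::runif(n, 0.005, 0.025))
  tibble::tibble(
    collar_id = seq_len(n),
    chamber_trt = trt$chamber_trt[idx],
    nutrient_trt = trt$nutrient_trt[idx],
    treatment = paste(trt$chamber_trt[idx], trt$nutrient_trt[idx]),
    volume_m3 = cfg$chamber_volume + cfg$collar_area * rim,
    area_m2 = cfg$collar_area
  )
}

#' Stage windows implied by a configuration
#'
#' @param cfg A `sim_config`.
#' @return A tibble with `stage`, `start`, `end` (inclusive dates); each
#'   stage ends the day before the next begins, S4 on `end_date`.
#' @export
stage_windows <- function(cfg) {
  sb <- cfg$stage_boundaries
  tibble::tibble(
    stage = names(sb),
    start = unname(sb),
    end = c(unname(sb[-1]) - 1, cfg$end_date)
  )
}

# Evaluate `expr` under a deterministic per-collar RNG substream, restoring
# the caller's RNG state afterwards. Substream seeds are a fixed affine map
# of (seed, collar) kept below 2^31.
with_collar_seed <- function(seed, collar, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(collar))
  expr
}
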