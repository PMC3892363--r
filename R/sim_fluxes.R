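#' Logistic shoot/root growth trajectory
#'
#' Shoot dry weight is zero before germination (sowing date +
#' `germination_lag_days`) and follows a logistic curve afterwards; root dry
#' weight shares the trajectory scaled to its own asymptote. A per-collar
#' multiplier (mean 1) represents biological replication.
#'
#' @param timestamp POSIXct vector.
#' @param cfg A [sim_config()].
#' @param collar_effect Per-collar multiplier on the trajectory (default 1).
#' @return A tibble with `shoot_dw` and `root_dw` (g per collar).
#' @export
growth_trajectory <- function(timestamp, cfg, collar_effect = 1) {
  germ <- as.POSIXct(paste(cfg$sowing_date + cfg$germination_lag_days,
                           "00:00:00"), tz = "UTC")
  d <- as.numeric(difftime(timestamp, germ, units = "days"))
  w <- 1 / (1 + exp(-cfg$growth_rate * (d - cfg$growth_midpoint_days)))
  w[d < 0] <- 0
  tibble::tibble(shoot_dw = collar_effect * cfg$shoot_dw_max * w,
                 root_dw = collar_effect * cfg$root_dw_max * w)
}

#' Canopy gross uptake at a given PAR and shoot biomass
#'
#' The reference light response is `a * log(PAR) + c`, clipped at zero below
#' its zero crossing; biomass scales its amplitude linearly through
#' `shoot_dw / gpp_ref_dw` (the reference shoot dry weight at which the
#' canopy would achieve the full reference response), so the shape of the
#' light response is independent of the biomass scaling.
#'
#' @param par PAR, umol m^-2 s^-1 (>= 0).
#' @param shoot_dw Shoot dry weight, g.
#' @param cfg A [sim_config()].
#' @return Gross uptake, umol CO2 m^-2 s^-1 (>= 0).
#' @export
canopy_gpp <- function(par, shoot_dw, cfg) {
  f <- ifelse(par > 0, cfg$lr_coeff_a * log(pmax(par, 1e-12)) + cfg$lr_coeff_c, 0)
  (shoot_dw / cfg$gpp_ref_dw) * pmax(f, 0)
}

#' Generate the true (unobserved) hourly flux series
#'
#' Forward model for every collar-hour, micrometeorological sign convention
#' (flux from biosphere to atmosphere positive):
#' \itemize{
#'   \item heterotrophic respiration `Rhet = rh0 * q10_het^((T5 - tref)/10)`
#'     driven by soil temperature at 5 cm;
#'   \item autotrophic respiration
#'     `Rauto = rauto_coeff * shoot_dw * q10_auto^((Tair - tref)/10)`,
#'     multiplied by `suppression_s` while PAR > 0 (daytime suppression of
#'     dark respiration);
#'   \item `Reco = Rhet + Rauto`; `GPP = canopy_gpp(PAR, shoot_dw)`;
#'     `NEE = Reco - GPP` exactly.
#' }
#'
#' @param cfg A [sim_config()].
#' @param env Environment series from [generate_environment()]; must cover
#'   the configured run.
#' @return A tibble with one row per collar-hour: `collar_id`, `timestamp`,
#'   `shoot_dw`, `root_dw`, `rhet`, `rauto`, `reco`, `gpp`, `nee`
#'   (umol CO2 m^-2 s^-1) plus the driving `par_out`, `t_air_c`, `t_soil5_c`.
#' @export
generate_true_fluxes <- function(cfg, env) {
  validate_sim_config(cfg)
  stopifnot(is.data.frame(env))
  if (any(env$par_out < 0) || any(!is.finite(env$t_air_c))) {
    stop("environment series has negative PAR or non-finite temperature",
         call. = FALSE)
  }
  if (as.Date(min(env$timestamp), tz = "UTC") > cfg$start_date ||
      as.Date(max(env$timestamp), tz = "UTC") < cfg$end_date) {
    stop("environment series does not cover the configured run", call. = FALSE)
  }

  effects <- collar_effects(cfg)
  out <- lapply(seq_len(cfg$n_collars), function(k) {
    gw <- growth_trajectory(env$timestamp, cfg, effects[k])
    rhet <- cfg$rh0 * cfg$q10_het^((env$t_soil5_c - cfg$tref) / 10)
    supp <- ifelse(env$par_out > 0, cfg$suppression_s, 1)
    rauto <- cfg$rauto_coeff * gw$shoot_dw *
      cfg$q10_auto^((env$t_air_c - cfg$tref) / 10) * supp
    gpp <- canopy_gpp(env$par_out, gw$shoot_dw, cfg)
    tibble::tibble(
      collar_id = k,
      timestamp = env$timestamp,
      shoot_dw = gw$shoot_dw,
      root_dw = gw$root_dw,
      rhet = rhet,
      rauto = rauto,
      reco = rhet + rauto,
      gpp = gpp,
      nee = rhet + rauto - gpp,
      par_out = env$par_out,
      t_air_c = env$t_air_c,
      t_soil5_c = env$t_soil5_c
    )
  })
  dplyr::bind_rows(out)
}

# lognormal per-collar growth multipliers, mean ~1, CV = biomass_cv,
# one substream per collar so collar k's draw never depends on n_collars
collar_effects <- function(cfg) {
  if (cfg$biomass_cv == 0) return(rep(1, cfg$n_collars))
  sdlog <- sqrt(log(1 + cfg$biomass_cv^2))
  vapply(seq_len(cfg$n_collars), function(k) {
    with_collar_seed(cfg$rng_seed, k, stats::rlnorm(1, -sdlog^2 / 2, sdlog))
  }, numeric(1))
}
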