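#' Synthesize a single chamber closure trace
#'
#' Observation model for one closure: the CO2 concentration is
#' `C(t) = C0 + m t + mixing transient + drawdown + noise`, where `m` is the
#' ppm s^-1 slope implied by the flux through the ideal-gas closed-chamber
#' conversion (the exact inverse of [concentration_slope_to_flux()]). The
#' mixing transient is an exponentially decaying term (10 s e-folding) whose
#' rate contribution is confined to the first 20 s of closure; for opaque
#' chambers closed in daylight an additional decaying photosynthetic
#' drawdown (pre-closure canopy uptake decaying with e-folding
#' `drawdown_efold_s`) acts over the first 50 s. Both terms are constant
#' beyond their windows, so a fit that discards the matching dead band
#' recovers `m` exactly in the noise-free case.
#'
#' @param flux Generating flux, umol CO2 m^-2 s^-1 (micromet sign).
#' @param cfg A [sim_config()].
#' @param chamber_type `"transparent"` or `"opaque"`.
#' @param par_out Ambient PAR during the closure (umol m^-2 s^-1).
#' @param t_air_c Air temperature, degrees C.
#' @param volume_m3,area_m2 Chamber system volume and collar area; default
#'   to the configured values.
#' @param gpp_ambient Pre-closure canopy uptake (umol m^-2 s^-1); source of
#'   the opaque daytime drawdown term.
#' @param c0 Starting concentration, ppm (default `baseline_co2`).
#' @return A `chamber_trace`: a list with `samples` (tibble of `t_s`,
#'   `co2_ppm` at 1 Hz over `trace_length_s`), chamber metadata
#'   (`chamber_type`, `volume_m3`, `area_m2`, `t_air_c`, `pressure_pa`,
#'   `par_in`, `par_out`) and the generating `slope_ppm_s`.
#' @export
#' @examples
#' tr <- synthesize_trace(1.5, noise_free(sim_config()), "opaque")
#' coef(lm(co2_ppm ~ t_s, tr$samples[tr$samples$t_s >= 50, ]))[2]
synthesize_trace <- function(flux, cfg, chamber_type = c("transparent", "opaque"),
                             par_out = 0, t_air_c = 10,
                             volume_m3 = cfg$chamber_volume,
                             area_m2 = cfg$collar_area,
                             gpp_ambient = 0, c0 = cfg$baseline_co2) {
  chamber_type <- match.arg(chamber_type)
  stopifnot(is.finite(flux))
  if (cfg$trace_length_s <= 0) stop("non-positive trace length", call. = FALSE)
  t <- as.numeric(seq(0, cfg$trace_length_s - 1))
  ppm_per_flux <- slope_flux_factor(volume_m3, area_m2, t_air_c + 273.15,
                                    cfg$pressure_pa)
  m <- flux * ppm_per_flux
  co2 <- c0 + m * t + trace_transient(t, cfg)
  if (chamber_type == "opaque" && par_out > 0 && gpp_ambient > 0) {
    co2 <- co2 + trace_drawdown(t, gpp_ambient * ppm_per_flux, cfg)
  }
  if (cfg$trace_sigma > 0) co2 <- co2 + stats::rnorm(length(t), 0, cfg$trace_sigma)
  structure(list(
    samples = tibble::tibble(t_s = t, co2_ppm = co2),
    chamber_type = chamber_type,
    volume_m3 = volume_m3,
    area_m2 = area_m2,
    t_air_c = t_air_c,
    pressure_pa = cfg$pressure_pa,
    par_in = if (chamber_type == "transparent") cfg$par_transmission * par_out else 0,
    par_out = par_out,
    slope_ppm_s = m
  ), class = "chamber_trace")
}

# ppm s^-1 per (umol m^-2 s^-1): R T A / (P V)
slope_flux_factor <- function(volume_m3, area_m2, t_k, pressure_pa) {
  8.314 * t_k * area_m2 / (pressure_pa * volume_m3)
}

# mixing transient: rate amp/10 * exp(-t/10) confined to t < 20 s,
# concentration term continuous and flat beyond 20 s
trace_transient <- function(t, cfg) {
  cfg$transient_amp * exp(-pmin(t, 20) / 10)
}

# photosynthetic drawdown after darkening: uptake rate u*exp(-t/tau)
# confined to t < 50 s; integral, flat beyond 50 s
trace_drawdown <- function(t, u_ppm_s, cfg) {
  tau <- cfg$drawdown_efold_s
  -u_ppm_s * tau * (1 - exp(-pmin(t, 50) / tau))
}

#' Synthesize the full season of chamber traces
#'
#' Schedules hourly closures for every collar (opaque-only during the
#' pre-sowing soil-only period, paired transparent-then-opaque afterwards;
#' closures staggered across collars as a multiplexer would) and emits the
#' 1 Hz CO2 traces with the same observation model as
#' [synthesize_trace()]. The transparent chamber observes
#' `NEE = Reco - GPP(tau * PAR)`, i.e. photosynthesis under the attenuated
#' lid light; the opaque chamber observes `Reco` with the daytime drawdown
#' transient. Recorded PAR carries sensor noise; `par_in` is exactly
#' `tau * par_out` when sensor noise is zero.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional precomputed [generate_true_fluxes()] output.
#' @param env Optional precomputed [generate_environment()] output.
#' @return A tibble in the `traces.csv` dialect: `closure_id`, `collar_id`,
#'   `chamber_type`, `timestamp` (closure start), `t_s`, `co2_ppm`,
#'   `par_in`, `par_out`, `t_air_c`. The closure-level schedule (generating
#'   flux and slope per closure) is attached as attribute `"closures"`.
#' @export
synthesize_traces <- function(cfg, truth = NULL, env = NULL) {
  validate_sim_config(cfg)
  if (is.null(env)) env <- generate_environment(cfg)
  if (is.null(truth)) truth <- generate_true_fluxes(cfg, env)
  meta <- collar_metadata(cfg)
  len <- cfg$trace_length_s
  tgrid <- as.numeric(seq(0, len - 1))
  first_nee_day <- cfg$sowing_date + 1

  per_collar <- lapply(seq_len(cfg$n_collars), function(k) {
    tr <- truth[truth$collar_id == k, ]
    date <- as.Date(tr$timestamp, tz = "UTC")
    vol <- meta$volume_m3[k]
    ppm_per_flux <- slope_flux_factor(vol, meta$area_m2[k],
                                      tr$t_air_c + 273.15, cfg$pressure_pa)
    # transparent chamber sees GPP at lid-attenuated PAR
    nee_lid <- tr$reco - canopy_gpp(cfg$par_transmission * tr$par_out,
                                    tr$shoot_dw, cfg)
    sched_t <- tibble::tibble(
      hour_ts = tr$timestamp, chamber_type = "transparent",
      offset_s = (k - 1) * 240, flux = nee_lid,
      gpp_ambient = 0, keep = date >= first_nee_day,
      par_true = tr$par_out, t_air_c = tr$t_air_c, ppm_per_flux = ppm_per_flux
    )
    sched_o <- tibble::tibble(
      hour_ts = tr$timestamp, chamber_type = "opaque",
      offset_s = (k - 1) * 240 + 120, flux = tr$reco,
      gpp_ambient = tr$gpp, keep = TRUE,
      par_true = tr$par_out, t_air_c = tr$t_air_c, ppm_per_flux = ppm_per_flux
    )
    sched <- rbind(sched_t[sched_t$keep, ], sched_o)
    sched <- sched[order(sched$hour_ts, sched$offset_s), ]
    nc <- nrow(sched)

    with_collar_seed(cfg$rng_seed, k, {
      c0 <- cfg$baseline_co2 + stats::rnorm(nc, 0, cfg$baseline_co2_sd)
      day <- sched$par_true > 0
      po <- sched$par_true
      pi_ <- ifelse(sched$chamber_type == "transparent",
                    cfg$par_transmission * sched$par_true, 0)
      if (cfg$sensor_sigma_par > 0) {
        po[day] <- pmax(0, po[day] + stats::rnorm(sum(day), 0, cfg$sensor_sigma_par))
        tday <- day & sched$chamber_type == "transparent"
        pi_[tday] <- pmax(0, pi_[tday] + stats::rnorm(sum(tday), 0,
                                                      cfg$sensor_sigma_par))
      }
      noise <- if (cfg$trace_sigma > 0) {
        stats::rnorm(nc * len, 0, cfg$trace_sigma)
      } else numeric(nc * len)

      m <- sched$flux * sched$ppm_per_flux
      u <- ifelse(sched$chamber_type == "opaque" & day & sched$gpp_ambient > 0,
                  sched$gpp_ambient * sched$ppm_per_flux, 0)
      idx <- rep(seq_len(nc), each = len)
      tt <- rep(tgrid, nc)
      co2 <- c0[idx] + m[idx] * tt + trace_transient(tt, cfg) +
        (-u[idx] * cfg$drawdown_efold_s *
           (1 - exp(-pmin(tt, 50) / cfg$drawdown_efold_s))) + noise

      closure_id <- sprintf("c%02d_%s_%s", k,
                            format(sched$hour_ts, "%Y%m%d%H", tz = "UTC"),
                            substr(sched$chamber_type, 1, 1))
      closures <- tibble::tibble(
        closure_id = closure_id,
        collar_id = k,
        chamber_type = sched$chamber_type,
        timestamp = sched$hour_ts + sched$offset_s,
        true_flux = sched$flux,
        slope_ppm_s = m,
        par_in = pi_,
        par_out = po,
        t_air_c = sched$t_air_c,
        volume_m3 = vol,
        area_m2 = meta$area_m2[k]
      )
      traces <- tibble::tibble(
        closure_id = closure_id[idx],
        collar_id = k,
        chamber_type = sched$chamber_type[idx],
        timestamp = closures$timestamp[idx],
        t_s = tt,
        co2_ppm = co2,
        par_in = pi_[idx],
        par_out = po[idx],
        t_air_c = sched$t_air_c[idx]
      )
      list(traces = traces, closures = closures)
    })
  })

  traces <- dplyr::bind_rows(lapply(per_collar, `[[`, "traces"))
  closures <- dplyr::bind_rows(lapply(per_collar, `[[`, "closures"))
  attr(traces, "closures") <- closures
  traces
}
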