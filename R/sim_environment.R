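#' Generate hourly environmental drivers
#'
#' Produces the hourly sensor series the chamber system would log over the
#' run: air temperature, soil temperature at the surface, 2 cm and 5 cm
#' depth, ambient PAR, and an hourly rain flag.
#'
#' Temperatures are diurnal sinusoids (progressively damped and lagged with
#' depth) plus AR(1) noise sharing a slow synoptic component across depths.
#' PAR is a clear-sky half-sine over the daylight window scaled by a daily
#' cloudiness factor `1 - cloud_depth * Beta(2, 2)`; it is exactly zero
#' between sunset and sunrise. Rain follows a two-state hourly Markov chain.
#' With all noise levels at zero the series are exactly the deterministic
#' sinusoid / clear-sky curves.
#'
#' @param cfg A [sim_config()].
#' @return A tibble (one row per hour, no gaps) with columns `timestamp`
#'   (POSIXct, UTC), `t_air_c`, `t_surf_c`, `t_soil2_c`, `t_soil5_c`,
#'   `par_out` (umol m^-2 s^-1, >= 0) and `rain` (logical).
#' @export
#' @examples
#' env <- generate_environment(sim_config(end_date = "2006-11-05"))
#' range(env$par_out)
generate_environment <- function(cfg) {
  validate_sim_config(cfg)
  ts <- seq(as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(cfg$end_date, "23:00:00"), tz = "UTC"),
            by = "hour")
  n <- length(ts)
  hod <- as.numeric(format(ts, "%H", tz = "UTC"))
  day <- as.integer(as.Date(ts, tz = "UTC") - cfg$start_date) + 1L

  with_collar_seed(cfg$rng_seed, 0L, {
    # shared synoptic weather component (slow AR(1)), plus faster local noise
    syn <- ar1_noise(n, rho = 0.98, sd = cfg$temp_sigma)
    loc <- ar1_noise(n, rho = cfg$temp_rho, sd = cfg$temp_sigma * 0.6)

    diurnal <- function(amp_frac, peak_h) {
      cfg$tamp_c * amp_frac * cos(2 * pi * (hod - peak_h) / 24)
    }
    t_air <- cfg$tmean_c + diurnal(1, 14) + syn + loc
    t_surf <- cfg$tmean_c + diurnal(0.7, 15) + 0.8 * syn + 0.5 * loc
    t_soil2 <- cfg$tmean_c + diurnal(0.5, 16) + 0.6 * syn + 0.25 * loc
    t_soil5 <- cfg$tmean_c + diurnal(0.35, 17) + 0.5 * syn + 0.1 * loc

    ndays <- max(day)
    cloud <- 1 - cfg$cloud_depth * stats::rbeta(ndays, 2, 2)
    par_out <- clear_sky_par(hod, cfg) * cloud[day]

    rain <- logical(n)
    u <- stats::runif(n)
    rain[1] <- u[1] < rain_stationary(cfg)
    for (i in seq_len(n)[-1]) {
      p <- if (rain[i - 1]) cfg$rain_p11 else cfg$rain_p01
      rain[i] <- u[i] < p
    }

    tibble::tibble(
      timestamp = ts,
      t_air_c = t_air,
      t_surf_c = t_surf,
      t_soil2_c = t_soil2,
      t_soil5_c = t_soil5,
      par_out = par_out,
      rain = rain
    )
  })
}

#' Clear-sky hourly PAR curve
#'
#' Half-sine over the daylight window evaluated at mid-hour, zero outside.
#' Exposed so tests can compare generated PAR with its analytic expectation.
#'
#' @param hour_of_day Numeric vector of hours (0-23).
#' @param cfg A [sim_config()].
#' @return PAR, umol m^-2 s^-1.
#' @export
clear_sky_par <- function(hour_of_day, cfg) {
  dl <- cfg$sunset_h - cfg$sunrise_h
  frac <- (hour_of_day + 0.5 - cfg$sunrise_h) / dl
  p <- cfg$par_max * sin(pi * pmin(pmax(frac, 0), 1))
  p[hour_of_day + 0.5 <= cfg$sunrise_h | hour_of_day + 0.5 >= cfg$sunset_h] <- 0
  p
}

# stationary wet-hour probability of the rain Markov chain
rain_stationary <- function(cfg) {
  if (cfg$rain_p01 == 0 && cfg$rain_p11 == 0) return(0)
  cfg$rain_p01 / (cfg$rain_p01 + 1 - cfg$rain_p11)
}

ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- z[1] * sd
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + sd * sqrt(1 - rho^2) * z[i]
  x
}
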