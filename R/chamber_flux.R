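#' Default dead band and calculation window by chamber type
#'
#' Opaque (dark) chambers need a 50 s dead band because photosynthesis
#' continues briefly after the lid darkens the canopy; transparent (NEE)
#' chambers only need the 20 s air-mixing period. The calculation window is
#' 90 s for both.
#'
#' @param chamber_type `"transparent"` or `"opaque"`.
#' @return A list with `deadband_s` and `window_s` (seconds).
#' @export
#' @examples
#' default_deadband("opaque")$deadband_s   # 50
#' default_deadband("transparent")$deadband_s  # 20
default_deadband <- function(chamber_type) {
  if (length(chamber_type) != 1 ||
      !chamber_type %in% c("transparent", "opaque")) {
    stop("unknown chamber type: ", paste(chamber_type, collapse = ", "),
         call. = FALSE)
  }
  list(deadband_s = if (chamber_type == "opaque") 50 else 20, window_s = 90)
}

#' Ordinary least-squares slope of a closure trace
#'
#' Fits the linear CO2 change over the half-open calculation interval
#' `[deadband_s, deadband_s + window_s)` and returns the slope with its
#' goodness of fit and standard error. Insufficient samples yield an
#' explicit failure result (`ok = FALSE`, `NA` slope), never a silent zero.
#'
#' @param trace A `chamber_trace` from [synthesize_trace()], or a data frame
#'   with columns `t_s` and `co2_ppm`.
#' @param deadband_s,window_s Dead band and window, seconds; defaults from
#'   [default_deadband()] when `trace` is a `chamber_trace`.
#' @param min_samples Minimum samples required in the window.
#' @return A list with `slope_ppm_s`, `intercept`, `r2`, `slope_se`, `n`,
#'   `deadband_s`, `window_s`, `ok`.
#' @export
fit_trace_slope <- function(trace, deadband_s = NULL, window_s = NULL,
                            min_samples = 10) {
  if (inherits(trace, "chamber_trace")) {
    dflt <- default_deadband(trace$chamber_type)
    if (is.null(deadband_s)) deadband_s <- dflt$deadband_s
    if (is.null(window_s)) window_s <- dflt$window_s
    samples <- trace$samples
  } else {
    samples <- trace
    if (is.null(deadband_s) || is.null(window_s)) {
      stop("`deadband_s` and `window_s` are required for raw samples",
           call. = FALSE)
    }
  }
  stopifnot(window_s > 0)
  keep <- samples$t_s >= deadband_s & samples$t_s < deadband_s + window_s
  t <- samples$t_s[keep]
  y <- samples$co2_ppm[keep]
  n <- length(t)
  fail <- list(slope_ppm_s = NA_real_, intercept = NA_real_, r2 = NA_real_,
               slope_se = NA_real_, n = n, deadband_s = deadband_s,
               window_s = window_s, ok = FALSE)
  if (n < min_samples) return(fail)
  ols_line(t, y, deadband_s, window_s)
}

# closed-form simple OLS with r2 and slope SE; shared by the scalar and
# batch fitters so both are the normal-equation solution
ols_line <- function(t, y, deadband_s, window_s) {
  n <- length(t)
  tm <- mean(t)
  ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  syy <- sum((y - ym)^2)
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  se <- if (n > 2) sqrt(pmax(rss, 0) / ((n - 2) * sxx)) else NA_real_
  list(slope_ppm_s = slope, intercept = ym - slope * tm, r2 = r2,
       slope_se = se, n = n, deadband_s = deadband_s, window_s = window_s,
       ok = TRUE)
}

#' Convert a concentration slope to an areal CO2 flux
#'
#' Ideal-gas closed-chamber conversion
#' `F = slope * P * V / (R * T * A)` with `R = 8.314` J mol^-1 K^-1: a slope
#' in umol mol^-1 s^-1 (ppm s^-1, dry mole fraction) yields a flux in
#' umol CO2 m^-2 s^-1. Linear in slope and volume, inverse in area and
#' temperature.
#'
#' @param slope_ppm_s Concentration slope, ppm s^-1.
#' @param volume_m3 Chamber system volume, m^3.
#' @param area_m2 Collar area, m^2.
#' @param t_k Air temperature, K.
#' @param pressure_pa Pressure, Pa.
#' @return Flux, umol CO2 m^-2 s^-1 (positive = release).
#' @export
#' @examples
#' concentration_slope_to_flux(0.05, 0.00482, 0.0314, 283.15, 101325)  # 0.330
concentration_slope_to_flux <- function(slope_ppm_s, volume_m3, area_m2,
                                        t_k, pressure_pa = 101325) {
  if (any(!is.finite(c(slope_ppm_s, volume_m3, area_m2, t_k, pressure_pa)))) {
    stop("non-finite input to flux conversion", call. = FALSE)
  }
  stopifnot(all(volume_m3 > 0), all(area_m2 > 0), all(t_k > 0),
            all(pressure_pa > 0))
  slope_ppm_s * pressure_pa * volume_m3 / (8.314 * t_k * area_m2)
}

#' Compute per-closure fluxes from a season of traces
#'
#' Applies [fit_trace_slope()] (vectorised over closures, identical closed
#' form) with the chamber-type default dead bands and converts slopes to
#' fluxes with the per-collar geometry. Closures whose fit fails are kept
#' with `NA` flux and a `fit_failed` flag.
#'
#' @param traces Long trace table in the `traces.csv` dialect (see
#'   [synthesize_traces()]).
#' @param geometry Per-collar geometry with `collar_id`, `volume_m3`,
#'   `area_m2` (e.g. [collar_metadata()]).
#' @param pressure_pa Barometric pressure, Pa.
#' @param deadbands Optional named list overriding the default dead bands,
#'   e.g. `list(transparent = 20, opaque = 50)`.
#' @param window_s Calculation window, seconds.
#' @param min_samples Minimum samples per window.
#' @return A flux-record tibble: `closure_id`, `collar_id`, `chamber_type`,
#'   `timestamp`, `flux` (umol m^-2 s^-1), `slope_ppm_s`, `r2`, `slope_se`,
#'   `deadband_s`, `window_s`, `n_samples`, `par_in`, `par_out`,
#'   `temperature_c`, `qc_flags` (empty string when clean).
#' @export
compute_fluxes <- function(traces, geometry, pressure_pa = 101325,
                           deadbands = NULL, window_s = 90,
                           min_samples = 10) {
  db_t <- if (!is.null(deadbands$transparent)) deadbands$transparent else
    default_deadband("transparent")$deadband_s
  db_o <- if (!is.null(deadbands$opaque)) deadbands$opaque else
    default_deadband("opaque")$deadband_s

  tr <- traces |>
    dplyr::mutate(.db = ifelse(.data$chamber_type == "opaque", db_o, db_t)) |>
    dplyr::filter(.data$t_s >= .data$.db, .data$t_s < .data$.db + window_s)

  fits <- tr |>
    dplyr::group_by(.data$closure_id) |>
    dplyr::summarise(
      collar_id = .data$collar_id[1],
      chamber_type = .data$chamber_type[1],
      timestamp = .data$timestamp[1],
      par_in = .data$par_in[1],
      par_out = .data$par_out[1],
      temperature_c = .data$t_air_c[1],
      deadband_s = .data$.db[1],
      n_samples = dplyr::n(),
      .sxx = sum((.data$t_s - mean(.data$t_s))^2),
      .sxy = sum((.data$t_s - mean(.data$t_s)) *
                   (.data$co2_ppm - mean(.data$co2_ppm))),
      .syy = sum((.data$co2_ppm - mean(.data$co2_ppm))^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      slope_ppm_s = .data$.sxy / .data$.sxx,
      .rss = .data$.syy - .data$slope_ppm_s * .data$.sxy,
      r2 = ifelse(.data$.syy > 0, 1 - .data$.rss / .data$.syy, NA_real_),
      slope_se = ifelse(.data$n_samples > 2,
                        sqrt(pmax(.data$.rss, 0) /
                               ((.data$n_samples - 2) * .data$.sxx)),
                        NA_real_),
      window_s = window_s
    )

  bad <- fits$n_samples < min_samples
  fits$slope_ppm_s[bad] <- NA_real_
  fits$r2[bad] <- NA_real_
  fits$slope_se[bad] <- NA_real_

  fits <- dplyr::left_join(fits, geometry[, c("collar_id", "volume_m3",
                                              "area_m2")], by = "collar_id")
  fits$flux <- ifelse(is.na(fits$slope_ppm_s), NA_real_,
                      concentration_slope_to_flux(
                        ifelse(is.na(fits$slope_ppm_s), 0, fits$slope_ppm_s),
                        fits$volume_m3, fits$area_m2,
                        fits$temperature_c + 273.15, pressure_pa))
  fits$qc_flags <- ifelse(bad, "fit_failed", "")

  fits |>
    dplyr::select("closure_id", "collar_id", "chamber_type", "timestamp",
                  "flux", "slope_ppm_s", "r2", "slope_se", "deadband_s",
                  "window_s", "n_samples", "par_in", "par_out",
                  "temperature_c", "qc_flags") |>
    dplyr::arrange(.data$collar_id, .data$timestamp, .data$chamber_type)
}

#' Flag flux records for quality control
#'
#' Adds (never deletes) semicolon-joined flags to each record: `night` when
#' ambient PAR is below the night threshold, `rain` when the record's hour
#' is flagged rainy in the environment series, and `poor_fit` when the fit
#' r-squared is below threshold while the slope magnitude exceeds a noise
#' floor (near-zero slopes legitimately fit poorly). Downstream analyses
#' choose which flags to exclude.
#'
#' @param records Flux records from [compute_fluxes()].
#' @param env Environment series (for the rain flag); `NULL` skips rain
#'   flagging.
#' @param night_par Night threshold on `par_out`, umol m^-2 s^-1.
#' @param r2_min Minimum acceptable r-squared.
#' @param slope_noise_floor Slope magnitude (ppm s^-1) below which `poor_fit`
#'   is not applied.
#' @return `records` with `qc_flags` updated.
#' @export
qc_filter <- function(records, env = NULL, night_par = 5, r2_min = 0.75,
                      slope_noise_floor = 0.03) {
  add_flag <- function(flags, which, flag) {
    ifelse(which, ifelse(flags == "", flag, paste(flags, flag, sep = ";")),
           flags)
  }
  flags <- records$qc_flags
  if (is.null(flags)) flags <- rep("", nrow(records))
  flags <- add_flag(flags, !is.na(records$par_out) &
                      records$par_out < night_par, "night")
  if (!is.null(env)) {
    hour <- as.POSIXct(trunc(records$timestamp, "hours"))
    rain <- env$rain[match(hour, env$timestamp)]
    flags <- add_flag(flags, !is.na(rain) & rain, "rain")
  }
  flags <- add_flag(flags, !is.na(records$r2) & records$r2 < r2_min &
                      !is.na(records$slope_ppm_s) &
                      abs(records$slope_ppm_s) > slope_noise_floor, "poor_fit")
  records$qc_flags <- flags
  records
}

#' Convenience predicate: records free of the given flags
#'
#' @param records Flux records with `qc_flags`.
#' @param exclude Character vector of flags that disqualify a record.
#' @return Logical vector.
#' @export
qc_pass <- function(records, exclude = c("night", "rain", "poor_fit",
                                         "fit_failed")) {
  toks <- strsplit(ifelse(is.na(records$qc_flags), "", records$qc_flags), ";",
                   fixed = TRUE)
  !vapply(toks, function(x) any(x %in% exclude), logical(1))
}

#' Pair transparent and opaque closures into hourly (NEE, Reco) records
#'
#' Within each collar-hour the transparent record is paired with the opaque
#' record that follows it (the multiplexer measures the transparent chamber
#' first). Hours with only one chamber type are reported as unpaired rows,
#' not dropped; two closures of the same type in one collar-hour raise an
#' ambiguity error naming the closures.
#'
#' @param records Flux records sorted by time (any order is accepted; they
#'   are sorted internally).
#' @param flux_col Name of the flux column to carry into the pairs (e.g.
#'   `"flux"` or `"flux_corrected"`).
#' @return A tibble with one row per collar-hour: `collar_id`, `hour`
#'   (POSIXct), `nee`, `reco`, the contributing closure ids, and `paired`
#'   (both types present).
#' @export
pair_cycle <- function(records, flux_col = "flux") {
  rec <- records[order(records$collar_id, records$timestamp), ]
  rec$hour <- as.POSIXct(trunc(rec$timestamp, "hours"))
  dup <- rec |>
    dplyr::count(.data$collar_id, .data$hour, .data$chamber_type) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    ids <- rec |>
      dplyr::semi_join(dup, by = c("collar_id", "hour", "chamber_type"))
    stop("ambiguous closures (same chamber type twice in one collar-hour): ",
         paste(ids$closure_id, collapse = ", "), call. = FALSE)
  }
  wide <- rec |>
    dplyr::mutate(.flux = .data[[flux_col]]) |>
    dplyr::select("collar_id", "hour", "chamber_type", "closure_id",
                  ".flux", "timestamp") |>
    tidyr::pivot_wider(names_from = "chamber_type",
                       values_from = c(".flux", "closure_id", "timestamp"))
  for (col in c(".flux_transparent", ".flux_opaque",
                "closure_id_transparent", "closure_id_opaque",
                "timestamp_transparent", "timestamp_opaque")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (startsWith(col, ".flux")) NA_real_ else NA
    }
  }
  # enforce transparent-then-opaque ordering where both are present
  both <- !is.na(wide$.flux_transparent) & !is.na(wide$.flux_opaque)
  ooo <- both & !is.na(wide$timestamp_transparent) &
    !is.na(wide$timestamp_opaque) &
    wide$timestamp_opaque < wide$timestamp_transparent
  tibble::tibble(
    collar_id = wide$collar_id,
    hour = wide$hour,
    nee = wide$.flux_transparent,
    reco = wide$.flux_opaque,
    closure_id_nee = wide$closure_id_transparent,
    closure_id_reco = wide$closure_id_opaque,
    paired = both & !ooo
  )
}
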