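#' Select the temperature variable that best explains respiration
#'
#' Computes the Pearson correlation between `log(Reco)` and each candidate
#' temperature series and returns the best one. Ties are broken by the fixed
#' ordering of `candidates` (air first, then progressively deeper soil), so
#' the choice is deterministic.
#'
#' @param records Opaque (Reco) flux records with positive fluxes; records
#'   with `flux <= 0` or `NA` are ignored.
#' @param env Environment series providing the candidate columns, matched by
#'   the record's hour.
#' @param candidates Ordered candidate column names in `env`.
#' @param min_pairs Minimum paired observations required per candidate.
#' @return A list with `best` (column name) and `table` (tibble of
#'   candidate, correlation, n).
#' @export
select_temperature_driver <- function(records, env,
                                      candidates = c("t_air_c", "t_surf_c",
                                                     "t_soil2_c", "t_soil5_c"),
                                      min_pairs = 20) {
  have <- candidates[candidates %in% names(env)]
  if (length(have) == 0) stop("no candidate temperature series present",
                              call. = FALSE)
  hour <- as.POSIXct(trunc(records$timestamp, "hours"))
  idx <- match(hour, env$timestamp)
  ok <- !is.na(records$flux) & records$flux > 0 & !is.na(idx)
  lr <- log(records$flux[ok])
  rows <- lapply(have, function(v) {
    temp <- env[[v]][idx[ok]]
    keep <- is.finite(temp)
    n <- sum(keep)
    if (n < min_pairs) {
      tibble::tibble(candidate = v, correlation = NA_real_, n = n)
    } else {
      tibble::tibble(candidate = v,
                     correlation = stats::cor(lr[keep], temp[keep]), n = n)
    }
  })
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$correlation))) {
    stop("no candidate has enough paired observations", call. = FALSE)
  }
  best <- tab$candidate[which.max(tab$correlation)]  # first max wins ties
  list(best = best, table = tab)
}

#' Fit the exponential temperature response (Q10) of respiration
#'
#' Least-squares fit of `log(R) = log(a) + b * T` on positive respiration
#' fluxes; `Q10 = exp(10 b)` exactly, with its standard error by first-order
#' (delta-method) propagation `Q10 * 10 * SE(b)`. Non-positive fluxes are
#' excluded and counted, never log-transformed silently.
#'
#' @param flux Respiration fluxes, umol m^-2 s^-1.
#' @param temperature Matching temperatures, degrees C.
#' @param stage Optional stage label stored on the fit.
#' @param min_points Minimum positive fluxes required.
#' @return A `q10_fit`: list with `stage`, `a` (pre-exponential), `b`
#'   (per degree C), `q10`, `se_b`, `se_q10`, `r2` (in log space), `n`,
#'   `n_excluded`, `temp_range`.
#' @export
#' @examples
#' t <- seq(0, 15, by = 0.5)
#' fit_q10(0.17 * exp(0.09 * t), t)$q10  # 2.46
fit_q10 <- function(flux, temperature, stage = NA_character_,
                    min_points = 10) {
  keep <- is.finite(flux) & is.finite(temperature) & flux > 0
  n_excluded <- sum(is.finite(flux) & flux <= 0)
  y <- log(flux[keep])
  x <- temperature[keep]
  if (length(y) < min_points) {
    stop("fewer than ", min_points, " positive respiration fluxes in window",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  se_b <- suppressWarnings(summary(fit))$coefficients[2, 2]
  q10 <- exp(10 * b)
  structure(list(
    stage = stage,
    a = exp(unname(stats::coef(fit)[1])),
    b = b,
    q10 = q10,
    se_b = se_b,
    se_q10 = q10 * 10 * se_b,
    r2 = suppressWarnings(summary(fit))$r.squared,
    n = length(y),
    n_excluded = n_excluded,
    temp_range = range(x)
  ), class = "q10_fit")
}

#' Label records with developmental stages
#'
#' Assigns each record exactly one stage from the window table (see
#' [stage_windows()]); a boundary day belongs to the stage that starts on
#' it. Records outside every window are an error.
#'
#' @param records Data frame with a `timestamp` column.
#' @param windows Tibble with `stage`, `start`, `end` (inclusive dates).
#' @return `records` with a `stage` column added.
#' @export
segment_stages <- function(records, windows) {
  date <- as.Date(records$timestamp, tz = "UTC")
  stage <- rep(NA_character_, length(date))
  for (i in seq_len(nrow(windows))) {
    in_w <- date >= windows$start[i] & date <= windows$end[i]
    stage[in_w] <- windows$stage[i]
  }
  if (anyNA(stage)) {
    stop("records outside all stage windows: ",
         paste(utils::head(unique(date[is.na(stage)]), 5), collapse = ", "),
         call. = FALSE)
  }
  records$stage <- stage
  records
}

#' Fit stage-wise Q10 models
#'
#' Convenience wrapper: segments opaque respiration records into stages and
#' fits [fit_q10()] per stage against the given temperature variable,
#' returning a tidy table.
#'
#' @param records Opaque flux records.
#' @param env Environment series.
#' @param windows Stage windows.
#' @param temp_var Temperature column in `env` used for each stage; either a
#'   single name or a named vector per stage (the pre-sowing soil-only stage
#'   typically uses soil temperature at 5 cm, later stages air temperature).
#' @param min_points Passed to [fit_q10()].
#' @return A tibble with one row per stage: coefficients, `q10`, standard
#'   errors, `r2`, `n`.
#' @export
fit_stage_q10 <- function(records, env, windows, temp_var = "t_air_c",
                          min_points = 10) {
  rec <- segment_stages(records, windows)
  hour <- as.POSIXct(trunc(rec$timestamp, "hours"))
  idx <- match(hour, env$timestamp)
  rows <- lapply(windows$stage, function(s) {
    v <- if (length(temp_var) > 1) temp_var[[s]] else temp_var
    in_s <- rec$stage == s & !is.na(rec$flux)
    f <- fit_q10(rec$flux[in_s], env[[v]][idx[in_s]], stage = s,
                 min_points = min_points)
    tibble::tibble(stage = s, temp_var = v, a = f$a, b = f$b, q10 = f$q10,
                   se_b = f$se_b, se_q10 = f$se_q10, r2 = f$r2, n = f$n,
                   n_excluded = f$n_excluded)
  })
  dplyr::bind_rows(rows)
}

#' Estimate daytime suppression of dark respiration
#'
#' Fits the log-linear temperature model with an additive day indicator,
#' `log(R) = log(a) + b T + d * day`, on post-germination opaque fluxes.
#' `exp(d)` is the day:night respiration ratio at equal temperature; a ratio
#' below 1 indicates daytime suppression.
#'
#' @param flux Respiration fluxes (positive values used).
#' @param temperature Matching temperatures, degrees C.
#' @param day Logical day indicator (PAR above the night threshold).
#' @return A list with `ratio`, `se_ratio`, `d` (day coefficient), `se_d`,
#'   `b`, `n_day`, `n_night`, `p_value` (for d = 0).
#' @export
day_night_suppression <- function(flux, temperature, day) {
  keep <- is.finite(flux) & flux > 0 & is.finite(temperature) & !is.na(day)
  y <- log(flux[keep])
  x <- temperature[keep]
  d <- as.logical(day[keep])
  if (!any(d) || !all(d == FALSE | d == TRUE) || !any(!d)) {
    stop("need both day and night respiration records", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + d)
  sm <- suppressWarnings(summary(fit))$coefficients
  dc <- unname(stats::coef(fit)["dTRUE"])
  se_d <- sm["dTRUE", 2]
  list(ratio = exp(dc), se_ratio = exp(dc) * se_d, d = dc, se_d = se_d,
       b = unname(stats::coef(fit)["x"]), n_day = sum(d), n_night = sum(!d),
       p_value = sm["dTRUE", 4])
}

#' Partition paired NEE/Reco records into GPP
#'
#' Under the micromet sign convention gross uptake is `GPP = Reco - NEE`
#' (positive). Negative raw values (possible under noise, expected near zero
#' at night) are clipped at zero and counted.
#'
#' @param pairs Paired hourly records from [pair_cycle()] (needs `nee` and
#'   `reco`); unpaired rows are an error unless `drop_unpaired = TRUE`.
#' @param drop_unpaired Silently drop rows missing one member (default
#'   FALSE: error).
#' @return `pairs` with `gpp` and `gpp_clipped` columns; number of clipped
#'   hours attached as attribute `"n_clipped"`.
#' @export
partition_gpp <- function(pairs, drop_unpaired = FALSE) {
  if (!all(pairs$paired)) {
    if (!drop_unpaired) {
      stop("unpaired collar-hours present (", sum(!pairs$paired),
           "); pass drop_unpaired = TRUE to discard them", call. = FALSE)
    }
    pairs <- pairs[pairs$paired, ]
  }
  raw <- pairs$reco - pairs$nee
  pairs$gpp <- pmax(raw, 0)
  pairs$gpp_clipped <- raw < 0
  attr(pairs, "n_clipped") <- sum(raw < 0)
  pairs
}
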