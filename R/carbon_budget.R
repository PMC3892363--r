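#' Time-integrate hourly NEE fluxes to grams of carbon
#'
#' The flux balance is the plain cumulative sum of hourly mean fluxes:
#' `g C = sum(F_h) * 3600 s * 12.011e-6 g umol^-1 * A`. Missing hours are
#' linearly interpolated from same-collar neighbours up to `gap_max_h`
#' consecutive hours; longer gaps are an error naming their extent, and the
#' achieved coverage fraction is reported.
#'
#' @param timestamp Hourly POSIXct stamps of the available fluxes.
#' @param flux Hourly mean NEE, umol CO2 m^-2 s^-1 (micromet sign).
#' @param area_m2 Collar area.
#' @param period Optional POSIXct length-2 vector bounding the integration
#'   (defaults to the observed range).
#' @param gap_max_h Longest gap (hours) the linear interpolation may fill.
#' @param min_coverage Minimum fraction of hours that must be observed.
#' @return A list with `g_c`, `umol_sum` (the raw sum of hourly mean fluxes
#'   in umol m^-2 s^-1 units, a common field diagnostic), `coverage`,
#'   `n_hours`, `n_filled`.
#' @export
#' @examples
#' ts <- as.POSIXct("2006-12-01 10:00", tz = "UTC")
#' cumulative_flux_carbon(ts, 1, area_m2 = 0.0278)$g_c  # 1.202e-3
cumulative_flux_carbon <- function(timestamp, flux, area_m2,
                                   period = NULL, gap_max_h = 3,
                                   min_coverage = 0.9) {
  stopifnot(area_m2 > 0)
  ok <- !is.na(flux)
  timestamp <- timestamp[ok]
  flux <- flux[ok]
  if (length(flux) == 0) stop("no fluxes to integrate", call. = FALSE)
  if (is.null(period)) period <- range(timestamp)
  grid <- seq(period[1], period[2], by = "hour")
  f <- flux[match(grid, timestamp)]
  n_missing <- sum(is.na(f))
  coverage <- 1 - n_missing / length(grid)
  if (coverage < min_coverage) {
    stop(sprintf("flux coverage %.1f%% below the configured minimum %.1f%%",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  if (n_missing > 0) {
    gaps <- rle(is.na(f))
    too_long <- gaps$lengths[gaps$values] > gap_max_h
    if (any(too_long)) {
      ends <- cumsum(gaps$lengths)
      starts <- ends - gaps$lengths + 1
      bad <- which(gaps$values)[too_long]
      stop("unexplained flux gaps longer than ", gap_max_h, " h at: ",
           paste(format(grid[starts[bad]]), collapse = ", "), call. = FALSE)
    }
    f <- stats::approx(seq_along(grid)[!is.na(f)], f[!is.na(f)],
                       xout = seq_along(grid), rule = 2)$y
  }
  umol_sum <- sum(f)
  list(g_c = umol_sum * 3600 * 12.011e-6 * area_m2,
       umol_sum = umol_sum,
       coverage = coverage,
       n_hours = length(grid),
       n_filled = n_missing)
}

#' Carbon leached as DOC
#'
#' `sum(volume * concentration) / 1000` grams of carbon: order-invariant sum
#' over collection events.
#'
#' @param volume_l Event volumes, L (>= 0).
#' @param conc_mg_l Event DOC concentrations, mg L^-1 (>= 0).
#' @return g C.
#' @export
#' @examples
#' doc_carbon(c(0.65, 0.85, 1.70), 20)  # 0.064
doc_carbon <- function(volume_l, conc_mg_l) {
  if (length(volume_l) == 0) return(0)
  if (any(volume_l < 0, na.rm = TRUE) || any(conc_mg_l < 0, na.rm = TRUE)) {
    stop("negative DOC volume or concentration", call. = FALSE)
  }
  sum(volume_l * conc_mg_l) * 1e-3
}

#' Stock-inventory carbon balance (Eq.-1 convention)
#'
#' `-(dC_soil + C_shoot + C_root + C_DOC - C_seed)`: the negative multiplier
#' puts the inventory on the micromet flux scale, so a mesocosm that gained
#' carbon has a negative balance directly comparable to the cumulative flux
#' estimate.
#'
#' @param d_c_soil Soil carbon change (final - initial), g C; may be
#'   negative.
#' @param c_shoot,c_root,c_doc,c_seed Pool carbon contents, g C.
#' @return g C (negative = net gain by the mesocosm). Vectorised.
#' @export
#' @examples
#' stock_balance(-0.017, 0.694, 0.856, 0.056, 1.299)  # -0.290
stock_balance <- function(d_c_soil, c_shoot, c_root, c_doc, c_seed) {
  pools <- cbind(d_c_soil, c_shoot, c_root, c_doc, c_seed)
  if (any(!is.finite(pools))) stop("missing or non-finite pool", call. = FALSE)
  -(d_c_soil + c_shoot + c_root + c_doc - c_seed)
}

#' Carbon content of a dry-mass pool
#'
#' @param mass_g Dry mass, g.
#' @param c_fraction Carbon mass fraction in (0, 1).
#' @return g C.
#' @export
#' @examples
#' pool_carbon(2500, 0.005)  # 12.5 g C in the soil
#' pool_carbon(1.75, 0.405)  # 0.71 g C in the shoots
pool_carbon <- function(mass_g, c_fraction) {
  stopifnot(all(mass_g >= 0), all(c_fraction > 0), all(c_fraction < 1))
  mass_g * c_fraction
}

#' Areal sowing density
#'
#' @param mass_g Seed mass, g.
#' @param area_m2 Collar area, m^2.
#' @return g DW m^-2.
#' @export
#' @examples
#' sowing_density(3.1, 0.0278)  # ~112 g DW m^-2
sowing_density <- function(mass_g, area_m2) {
  stopifnot(all(area_m2 > 0))
  mass_g / area_m2
}

#' Assemble per-collar carbon budgets
#'
#' Combines the hourly (corrected) NEE series, DOC events and stock
#' inventory into one budget row per collar. The flux balance is cumulative
#' NEE carbon plus collected DOC carbon as a release-side term, so both
#' balances count the leaching loss once and remain commensurable with the
#' Eq.-1 stock balance.
#'
#' @param nee_hourly Tibble with `collar_id`, `hour` (POSIXct) and `nee`
#'   (umol m^-2 s^-1), one row per collar-hour.
#' @param doc_events DOC events (`collar_id`, `volume_l`, `conc_mg_l`).
#' @param inventory Stock inventory rows (`collar_id`, the five pools and
#'   optionally treatment labels).
#' @param area_m2 Collar area.
#' @param period Optional integration period (POSIXct length 2).
#' @param gap_max_h,min_coverage Passed to [cumulative_flux_carbon()].
#' @return A tibble with one row per collar: treatments (if present), both
#'   balances, their components and the integration coverage.
#' @export
carbon_budgets <- function(nee_hourly, doc_events, inventory, area_m2,
                           period = NULL, gap_max_h = 3, min_coverage = 0.9) {
  ids <- sort(unique(inventory$collar_id))
  rows <- lapply(ids, function(k) {
    nh <- nee_hourly[nee_hourly$collar_id == k, ]
    cum <- cumulative_flux_carbon(nh$hour, nh$nee, area_m2, period = period,
                                  gap_max_h = gap_max_h,
                                  min_coverage = min_coverage)
    de <- doc_events[doc_events$collar_id == k, , drop = FALSE]
    c_doc_flux <- if (nrow(de) > 0) doc_carbon(de$volume_l, de$conc_mg_l) else 0
    inv <- inventory[inventory$collar_id == k, ]
    tibble::tibble(
      collar_id = k,
      cum_nee_c = cum$g_c,
      umol_sum = cum$umol_sum,
      c_doc_flux = c_doc_flux,
      flux_balance = cum$g_c + c_doc_flux,
      stock_balance = stock_balance(inv$d_c_soil, inv$c_shoot, inv$c_root,
                                    inv$c_doc, inv$c_seed),
      d_c_soil = inv$d_c_soil,
      c_shoot = inv$c_shoot,
      c_root = inv$c_root,
      c_doc = inv$c_doc,
      c_seed = inv$c_seed,
      coverage = cum$coverage
    )
  })
  out <- dplyr::bind_rows(rows)
  trt_cols <- intersect(c("chamber_trt", "nutrient_trt", "treatment"),
                        names(inventory))
  if (length(trt_cols) > 0) {
    out <- dplyr::left_join(out,
                            inventory[, c("collar_id", trt_cols)],
                            by = "collar_id")
  }
  out
}

#' Compare flux-based and stock-based carbon balances
#'
#' Per-collar differences, group means, the paired t statistic for a zero
#' mean difference, RMSE about the 1:1 line, the OLS regression of flux on
#' stock balance, and one-way ANOVA F tests across treatment groups for
#' each balance type.
#'
#' @param budgets Output of [carbon_budgets()] (needs `flux_balance`,
#'   `stock_balance` and, for the ANOVA, a grouping column).
#' @param group Name of the grouping column (default `"treatment"`); `NULL`
#'   skips the group summaries and ANOVA.
#' @return A list: `per_collar`, `group_summary`, `paired` (mean
#'   difference, t, df, p), `rmse_1to1`, `fit` (slope/intercept of
#'   flux ~ stock), `anova` (per balance type: F, df, p).
#' @export
compare_balances <- function(budgets, group = "treatment") {
  stopifnot(nrow(budgets) >= 2)
  d <- budgets$flux_balance - budgets$stock_balance
  per_collar <- tibble::tibble(collar_id = budgets$collar_id,
                               flux_balance = budgets$flux_balance,
                               stock_balance = budgets$stock_balance,
                               difference = d)
  tt <- if (stats::sd(d) > 0) stats::t.test(d) else NULL
  paired <- list(mean_difference = mean(d),
                 sd_difference = stats::sd(d),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  rmse <- sqrt(mean(d^2))
  fit <- stats::lm(flux_balance ~ stock_balance, data = budgets)
  fit_out <- list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r2 = suppressWarnings(summary(fit))$r.squared)

  group_summary <- NULL
  anova_out <- NULL
  if (!is.null(group) && group %in% names(budgets)) {
    g <- factor(budgets[[group]])
    group_summary <- budgets |>
      dplyr::group_by(.group = .data[[group]]) |>
      dplyr::summarise(
        n = dplyr::n(),
        flux_mean = mean(.data$flux_balance),
        flux_sd = stats::sd(.data$flux_balance),
        stock_mean = mean(.data$stock_balance),
        stock_sd = stats::sd(.data$stock_balance),
        mean_difference = mean(.data$flux_balance - .data$stock_balance),
        .groups = "drop"
      ) |>
      dplyr::rename(!!group := ".group")
    if (any(table(g) < 2)) {
      stop("singleton treatment groups: ANOVA needs >= 2 collars per group",
           call. = FALSE)
    }
    if (nlevels(g) >= 2) {
      anova_out <- lapply(c(flux = "flux_balance", stock = "stock_balance"),
                          function(col) {
        a <- summary(stats::aov(budgets[[col]] ~ g))[[1]]
        list(F = a$`F value`[1], df_between = a$Df[1], df_within = a$Df[2],
             p_value = a$`Pr(>F)`[1])
      })
    }
  }
  list(per_collar = per_collar, group_summary = group_summary,
       paired = paired, rmse_1to1 = rmse, fit = fit_out, anova = anova_out)
}
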