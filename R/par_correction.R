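#' Fit the lid PAR-transmission (attenuation) model
#'
#' A transparent chamber lid transmits a fixed fraction of ambient light, so
#' transmission is estimated as the slope of a through-origin least-squares
#' regression of inside on outside PAR (an intercept would be physically
#' meaningless for a passive lid).
#'
#' @param par_out Ambient (outside) PAR, umol m^-2 s^-1.
#' @param par_in PAR measured under the lid.
#' @param min_pairs Minimum daytime pairs required.
#' @return An `attenuation_model`: list with `tau` (transmission),
#'   `attenuation` (`1 - tau`), `r2` (uncentred, through-origin), `n`.
#' @export
#' @examples
#' m <- fit_attenuation(c(100, 500, 1000), 0.66 * c(100, 500, 1000))
#' m$attenuation  # 0.34
fit_attenuation <- function(par_out, par_in, min_pairs = 10) {
  keep <- is.finite(par_out) & is.finite(par_in) & par_out > 0
  x <- par_out[keep]
  y <- par_in[keep]
  if (length(x) == 0) stop("no daylight PAR pairs (all-zero PAR)", call. = FALSE)
  if (length(x) < min_pairs) {
    stop("need at least ", min_pairs, " daytime PAR pairs", call. = FALSE)
  }
  tau <- sum(x * y) / sum(x * x)
  r2 <- 1 - sum((y - tau * x)^2) / sum(y^2)
  structure(list(tau = tau, attenuation = 1 - tau, r2 = r2, n = length(x)),
            class = "attenuation_model")
}

#' Fit the NEE light-response model
#'
#' Fits daytime transparent-chamber net uptake (`-flux`, stored positive)
#' against PAR. The default logarithmic form `uptake = a * log(PAR) + c` is
#' a least-squares line on `log(PAR)`; the rectangular hyperbola
#' `uptake = Amax * PAR / (k + PAR)` is available as an alternative and is
#' fitted by nonlinear least squares.
#'
#' @param records Daytime, QC-passing transparent flux records (a data frame
#'   with `flux` and a PAR column).
#' @param form `"log"` (default) or `"hyperbola"`.
#' @param par_col Which PAR column drives the fit (default `par_out`: the
#'   ambient level the uptake is regressed against, as when a single
#'   plot-level sensor pair is used).
#' @param min_points Fewer usable points than this refuses to fit.
#' @return A `light_response_model`: list with `form`, `coef` (named `a`,
#'   `c` or `Amax`, `k`), `r2`, `n`, `par_range`.
#' @export
fit_light_response <- function(records, form = c("log", "hyperbola"),
                               par_col = "par_out", min_points = 20) {
  form <- match.arg(form)
  par <- records[[par_col]]
  uptake <- -records$flux
  keep <- is.finite(par) & is.finite(uptake) & par > 0
  par <- par[keep]
  uptake <- uptake[keep]
  if (length(par) < min_points) {
    stop("need at least ", min_points, " usable daytime points to fit the ",
         "light response (have ", length(par), ")", call. = FALSE)
  }
  if (form == "log") {
    fit <- stats::lm(uptake ~ log(par))
    cf <- stats::coef(fit)
    coefs <- c(a = unname(cf[2]), c = unname(cf[1]))
    r2 <- suppressWarnings(summary(fit))$r.squared
  } else {
    start <- list(Amax = max(uptake), k = stats::median(par))
    fit <- stats::nls(uptake ~ Amax * par / (k + par), start = start,
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    cf <- stats::coef(fit)
    coefs <- c(Amax = unname(cf["Amax"]), k = unname(cf["k"]))
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((uptake - mean(uptake))^2)
  }
  structure(list(form = form, coef = coefs, r2 = r2, n = length(par),
                 par_range = range(par)),
            class = "light_response_model")
}

#' Evaluate a fitted light-response model
#'
#' @param object A `light_response_model`.
#' @param par PAR values, umol m^-2 s^-1 (> 0).
#' @param ... Unused.
#' @return Predicted uptake (positive), umol m^-2 s^-1.
#' @export
predict.light_response_model <- function(object, par, ...) {
  if (object$form == "log") {
    object$coef[["a"]] * log(par) + object$coef[["c"]]
  } else {
    object$coef[["Amax"]] * par / (object$coef[["k"]] + par)
  }
}

#' Light-attenuation correction offset
#'
#' The extra uptake the mesocosm would have shown at ambient light:
#' `delta(PAR_in) = f(PAR_in / tau) - f(PAR_in)` for the fitted uptake model
#' `f`. For the logarithmic form this is `a * log(1 / tau)`, a constant over
#' the whole PAR range; it is nonnegative whenever `f` is nondecreasing and
#' `tau <= 1`. Values of `PAR_in / tau` beyond the model's fitted domain are
#' still computed but flagged with a warning.
#'
#' @param model A `light_response_model`.
#' @param par_in PAR under the lid, umol m^-2 s^-1 (> 0).
#' @param tau Lid transmission in (0, 1].
#' @return Offset in uptake units (umol m^-2 s^-1), vectorised over
#'   `par_in`.
#' @export
#' @examples
#' m <- structure(list(form = "log", coef = c(a = 0.74, c = 3.51),
#'                     par_range = c(5, 1000)),
#'                class = "light_response_model")
#' correction_offset(m, 300, 0.66)  # 0.307 at any PAR
correction_offset <- function(model, par_in, tau) {
  stopifnot(tau > 0, tau <= 1)
  if (any(par_in <= 0)) stop("`par_in` must be positive", call. = FALSE)
  ambient <- par_in / tau
  if (!is.null(model$par_range) && any(ambient > model$par_range[2])) {
    warning("correction evaluated beyond the fitted PAR domain ",
            "(extrapolation)", call. = FALSE)
  }
  predict(model, ambient) - predict(model, par_in)
}

#' Detect the onset of net carbon uptake
#'
#' First date whose daily mean transparent-chamber NEE is negative
#' (micromet convention: net uptake). Used when the correction onset is not
#' supplied explicitly.
#'
#' @param records Transparent flux records.
#' @return A `Date`, or `NA` if the daily mean never turns negative.
#' @export
detect_uptake_onset <- function(records) {
  rec <- records[records$chamber_type == "transparent" & !is.na(records$flux), ]
  daily <- rec |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(nee = mean(.data$flux), .groups = "drop") |>
    dplyr::arrange(.data$date)
  i <- which(daily$nee < 0)[1]
  if (is.na(i)) NA else daily$date[i]
}

#' Apply the PAR-attenuation correction to NEE records
#'
#' For transparent daytime records on/after the onset date the corrected
#' flux is `flux - delta(PAR_in)` (more negative = more uptake). Opaque,
#' nighttime and pre-onset records are unchanged. The uncorrected flux is
#' retained; records eligible for correction but missing PAR are flagged
#' `missing_par`, left uncorrected and counted in the attached report.
#'
#' @param records Flux records.
#' @param model Fitted `light_response_model`.
#' @param tau Lid transmission.
#' @param onset_date Date from which the correction applies (e.g. the first
#'   net-uptake date); `NULL` auto-detects via [detect_uptake_onset()].
#' @param night_par Daytime threshold on `par_out`.
#' @param par_source `"par_in"` uses the recorded under-lid PAR;
#'   `"par_out"` reconstructs it as `tau * par_out`.
#' @return `records` plus `flux_corrected`, `correction_offset` and
#'   `corrected_flag` columns; counts of corrected/missing records are
#'   attached as attribute `"correction_report"`.
#' @export
apply_correction <- function(records, model, tau, onset_date = NULL,
                             night_par = 5,
                             par_source = c("par_in", "par_out")) {
  par_source <- match.arg(par_source)
  if (is.null(onset_date)) onset_date <- detect_uptake_onset(records)
  onset_date <- as.Date(onset_date)
  par_in <- if (par_source == "par_in") records$par_in else
    tau * records$par_out
  eligible <- records$chamber_type == "transparent" &
    !is.na(records$par_out) & records$par_out >= night_par &
    as.Date(records$timestamp, tz = "UTC") >= onset_date &
    !is.na(records$flux)
  missing_par <- eligible & (is.na(par_in) | par_in <= 0)
  do_corr <- eligible & !missing_par

  delta <- rep(0, nrow(records))
  if (any(do_corr)) {
    delta[do_corr] <- suppressWarnings(
      correction_offset(model, par_in[do_corr], tau))
  }
  records$correction_offset <- delta
  records$flux_corrected <- records$flux - delta
  records$corrected_flag <- do_corr
  if (any(missing_par)) {
    records$qc_flags <- ifelse(missing_par,
                               ifelse(records$qc_flags == "", "missing_par",
                                      paste(records$qc_flags, "missing_par",
                                            sep = ";")),
                               records$qc_flags)
  }
  attr(records, "correction_report") <- list(
    onset_date = onset_date, tau = tau,
    n_corrected = sum(do_corr), n_missing_par = sum(missing_par)
  )
  records
}
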