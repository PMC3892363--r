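#' @title CSV dialects
#' @description Readers and writers for the pipeline's tabular interchange
#'   files. One documented dialect each: comma-separated, '.' decimal
#'   separator, ISO-8601 UTC timestamps, UTF-8. Readers hard-fail on header
#'   mismatch and report malformed rows with their line numbers; unknown
#'   extra columns are preserved.
#' @name mesoflux-io
NULL

.dialects <- list(
  traces = list(req = c("closure_id", "collar_id", "chamber_type",
                        "timestamp", "t_s", "co2_ppm", "par_in", "par_out",
                        "t_air_c"),
                types = readr::cols(
                  closure_id = readr::col_character(),
                  collar_id = readr::col_integer(),
                  chamber_type = readr::col_character(),
                  timestamp = readr::col_datetime(),
                  t_s = readr::col_double(),
                  co2_ppm = readr::col_double(),
                  par_in = readr::col_double(),
                  par_out = readr::col_double(),
                  t_air_c = readr::col_double(),
                  .default = readr::col_guess())),
  env = list(req = c("timestamp", "t_air_c", "t_surf_c", "t_soil2_c",
                     "t_soil5_c", "par_out", "rain"),
             types = readr::cols(timestamp = readr::col_datetime(),
                                 rain = readr::col_logical(),
                                 .default = readr::col_double())),
  doc = list(req = c("collar_id", "date", "volume_l", "conc_mg_l"),
             types = readr::cols(collar_id = readr::col_integer(),
                                 date = readr::col_date(),
                                 .default = readr::col_double())),
  inventory = list(req = c("collar_id", "d_c_soil", "c_shoot", "c_root",
                           "c_doc", "c_seed"),
                   types = readr::cols(collar_id = readr::col_integer(),
                                       chamber_trt = readr::col_character(),
                                       nutrient_trt = readr::col_character(),
                                       treatment = readr::col_character(),
                                       .default = readr::col_double())),
  fluxes = list(req = c("closure_id", "collar_id", "chamber_type",
                        "timestamp", "flux", "slope_ppm_s", "r2", "slope_se",
                        "deadband_s", "window_s", "par_in", "par_out",
                        "temperature_c", "qc_flags"),
                types = readr::cols(closure_id = readr::col_character(),
                                    collar_id = readr::col_integer(),
                                    chamber_type = readr::col_character(),
                                    timestamp = readr::col_datetime(),
                                    qc_flags = readr::col_character(),
                                    corrected_flag = readr::col_logical(),
                                    n_samples = readr::col_integer(),
                                    .default = readr::col_double())),
  budgets = list(req = c("collar_id", "flux_balance", "stock_balance"),
                 types = readr::cols(collar_id = readr::col_integer(),
                                     chamber_trt = readr::col_character(),
                                     nutrient_trt = readr::col_character(),
                                     treatment = readr::col_character(),
                                     .default = readr::col_double())),
  truth = list(req = c("collar_id", "timestamp", "rhet", "rauto", "reco",
                       "gpp", "nee", "shoot_dw"),
               types = readr::cols(collar_id = readr::col_integer(),
                                   timestamp = readr::col_datetime(),
                                   .default = readr::col_double()))
)

read_dialect <- function(path, dialect) {
  spec <- .dialects[[dialect]]
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE, progress = FALSE))
  missing <- setdiff(spec$req, hdr)
  if (length(missing) > 0) {
    stop("header mismatch in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # numeric columns are read as text and converted through R's strtod so
  # values survive the round trip bit-exactly (fast CSV double parsers are
  # not correctly rounded in the last ulp)
  collectors <- spec$types$cols
  was_double <- vapply(collectors, inherits, logical(1), "collector_double")
  collectors[was_double] <- list(readr::col_character())
  types <- do.call(readr::cols,
                   c(collectors, .default = list(readr::col_character())))
  out <- suppressWarnings(
    readr::read_csv(path, col_types = types,
                    show_col_types = FALSE, progress = FALSE,
                    locale = readr::locale(decimal_mark = ".", tz = "UTC")))
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    stop("malformed rows in ", basename(path), " (line: expected/actual): ",
         paste(sprintf("%d: %s/%s", pr$row, pr$expected, pr$actual),
               collapse = "; "), call. = FALSE)
  }
  explicit_dbl <- names(collectors)[was_double]
  keep_text <- names(collectors)[!was_double]
  for (col in setdiff(names(out), keep_text)) {
    x <- out[[col]]
    if (!is.character(x)) next
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "NA" & is.na(v)
    if (any(bad)) {
      if (col %in% explicit_dbl || col %in% spec$req) {
        stop("malformed rows in ", basename(path),
             " (line: column/actual): ",
             paste(sprintf("%d: %s/%s", which(bad) + 1L, col, x[bad]),
                   collapse = "; "), call. = FALSE)
      }
      next  # unknown non-numeric column: preserve as text
    }
    out[[col]] <- v
  }
  out
}

write_dialect <- function(x, path, dialect) {
  spec <- .dialects[[dialect]]
  missing <- setdiff(spec$req, names(x))
  if (length(missing) > 0) {
    stop("refusing to write ", dialect, " file without column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # %.17g guarantees doubles survive the text round trip bit-exactly
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.double(x[[col]]) && !inherits(x[[col]], c("POSIXct", "Date"))) {
      x[[col]] <- ifelse(is.na(x[[col]]), NA_character_,
                         sprintf("%.17g", x[[col]]))
    }
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname mesoflux-io
#' @param path File path.
#' @export
read_traces <- function(path) read_dialect(path, "traces")

#' @rdname mesoflux-io
#' @param x Table to write (see the matching reader for required columns).
#' @export
write_traces <- function(x, path) write_dialect(x, path, "traces")

#' @rdname mesoflux-io
#' @export
read_env <- function(path) read_dialect(path, "env")

#' @rdname mesoflux-io
#' @export
write_env <- function(x, path) write_dialect(x, path, "env")

#' @rdname mesoflux-io
#' @export
read_doc <- function(path) read_dialect(path, "doc")

#' @rdname mesoflux-io
#' @export
write_doc <- function(x, path) write_dialect(x, path, "doc")

#' @rdname mesoflux-io
#' @export
read_inventory <- function(path) read_dialect(path, "inventory")

#' @rdname mesoflux-io
#' @export
write_inventory <- function(x, path) write_dialect(x, path, "inventory")

#' @rdname mesoflux-io
#' @export
read_fluxes <- function(path) read_dialect(path, "fluxes")

#' @rdname mesoflux-io
#' @export
write_fluxes <- function(x, path) write_dialect(x, path, "fluxes")

#' @rdname mesoflux-io
#' @export
read_budgets <- function(path) read_dialect(path, "budgets")

#' @rdname mesoflux-io
#' @export
write_budgets <- function(x, path) write_dialect(x, path, "budgets")

#' @rdname mesoflux-io
#' @export
read_truth <- function(path) read_dialect(path, "truth")

#' @rdname mesoflux-io
#' @export
write_truth <- function(x, path) write_dialect(x, path, "truth")
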