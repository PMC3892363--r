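#' Run the full chamber-flux analysis pipeline
#'
#' Executes the requested stages in order
#' `simulate -> flux -> correct -> q10 -> budget -> validate`, passing
#' artifacts through `out_dir` as CSV files so each stage is idempotent
#' given identical inputs. A later stage requested without its input files
#' present raises a dependency error naming the missing file. A run
#' manifest (`manifest.txt`) records the config hash, seed and row counts
#' per artifact. No stage mutates its inputs; every output is a new file.
#'
#' @param cfg A [sim_config()] (also carries the QC/correction/budget
#'   settings used by later stages).
#' @param out_dir Directory for artifacts (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "flux", "correct", "q10", "budget", "validate")`.
#' @param write_traces_file Whether the simulate stage also writes the
#'   (large) `traces.csv`; the in-memory hand-off to the flux stage does not
#'   need it, so the default only writes it when the flux stage is not run
#'   in the same call.
#' @param closure_tol_g Absolute flux-vs-stock closure tolerance (g C) used
#'   by the validate stage.
#' @return Invisibly, a list with the stage outputs that were produced
#'   (`fluxes`, `fluxes_corrected`, `q10_fits`, `budgets`, `comparison`,
#'   `validation`) and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "flux", "correct", "q10",
                                    "budget", "validate"),
                         write_traces_file = NULL,
                         closure_tol_g = NULL) {
  all_stages <- c("simulate", "flux", "correct", "q10", "budget", "validate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  need <- function(file, stage) {
    if (!file.exists(p(file))) {
      stop("stage `", stage, "` requires missing input: ", p(file),
           call. = FALSE)
    }
  }
  out <- list()
  counts <- list()

  traces <- NULL
  env <- NULL

  if ("simulate" %in% stages) {
    env <- generate_environment(cfg)
    truth <- generate_true_fluxes(cfg, env)
    traces <- synthesize_traces(cfg, truth = truth, env = env)
    doc <- generate_doc_events(cfg, env)
    inventory <- generate_stock_inventory(cfg, truth, doc)
    write_env(env, p("env.csv"))
    write_doc(doc, p("doc.csv"))
    write_inventory(inventory, p("inventory.csv"))
    write_truth(truth[, c("collar_id", "timestamp", "rhet", "rauto", "reco",
                          "gpp", "nee", "shoot_dw", "root_dw", "par_out",
                          "t_air_c", "t_soil5_c")], p("truth.csv"))
    if (is.null(write_traces_file)) {
      write_traces_file <- !("flux" %in% stages)
    }
    if (write_traces_file) write_traces(traces, p("traces.csv"))
    counts$env <- nrow(env)
    counts$doc <- nrow(doc)
    counts$inventory <- nrow(inventory)
    counts$truth <- nrow(truth)
  }

  if ("flux" %in% stages) {
    if (is.null(traces)) {
      need("traces.csv", "flux")
      traces <- read_traces(p("traces.csv"))
    }
    if (is.null(env)) {
      need("env.csv", "flux")
      env <- read_env(p("env.csv"))
    }
    geometry <- collar_metadata(cfg)
    fluxes <- compute_fluxes(traces, geometry,
                             pressure_pa = cfg$pressure_pa)
    fluxes <- qc_filter(fluxes, env, night_par = cfg$night_par)
    write_fluxes(fluxes, p("fluxes.csv"))
    out$fluxes <- fluxes
    counts$fluxes <- nrow(fluxes)
  }

  if ("correct" %in% stages) {
    if (is.null(out$fluxes)) {
      need("fluxes.csv", "correct")
      out$fluxes <- read_fluxes(p("fluxes.csv"))
    }
    fluxes <- out$fluxes
    day_t <- fluxes$chamber_type == "transparent" & qc_pass(fluxes)
    att <- fit_attenuation(fluxes$par_out[day_t], fluxes$par_in[day_t])
    # light response fitted over the net-uptake period (established canopy),
    # the same window the correction is applied to
    onset <- detect_uptake_onset(fluxes)
    if (!is.na(onset)) {
      lr_set <- day_t & as.Date(fluxes$timestamp, tz = "UTC") >= onset
      lr <- fit_light_response(fluxes[lr_set, ])
      corrected <- apply_correction(fluxes, lr, att$tau, onset_date = onset,
                                    night_par = cfg$night_par)
    } else {
      lr <- NULL
      corrected <- fluxes
      corrected$correction_offset <- 0
      corrected$flux_corrected <- corrected$flux
      corrected$corrected_flag <- FALSE
      attr(corrected, "correction_report") <-
        list(onset_date = NA, tau = att$tau, n_corrected = 0L,
             n_missing_par = 0L)
    }
    rep <- attr(corrected, "correction_report")
    write_fluxes(corrected, p("fluxes_corrected.csv"))
    writeLines(c(
      if (!is.null(lr)) c(
        sprintf("form: %s", lr$form),
        sprintf("a: %.6f", lr$coef[["a"]]),
        sprintf("c: %.6f", lr$coef[["c"]]),
        sprintf("r2: %.4f", lr$r2),
        sprintf("n: %d", lr$n)
      ) else "form: none (no net-uptake period detected)",
      sprintf("tau: %.6f", att$tau),
      sprintf("attenuation: %.6f", att$attenuation),
      sprintf("onset_date: %s", rep$onset_date),
      sprintf("n_corrected: %d", rep$n_corrected),
      sprintf("n_missing_par: %d", rep$n_missing_par)
    ), p("light_response.txt"))
    out$fluxes_corrected <- corrected
    out$attenuation <- att
    out$light_response <- lr
    counts$fluxes_corrected <- nrow(corrected)
  }

  if ("q10" %in% stages) {
    if (is.null(out$fluxes_corrected)) {
      need("fluxes_corrected.csv", "q10")
      out$fluxes_corrected <- read_fluxes(p("fluxes_corrected.csv"))
    }
    if (is.null(env)) {
      need("env.csv", "q10")
      env <- read_env(p("env.csv"))
    }
    fx <- out$fluxes_corrected
    opaque <- fx[fx$chamber_type == "opaque" & !is.na(fx$flux), ]
    tv <- c(S1 = "t_soil5_c", S2 = "t_air_c", S3 = "t_air_c", S4 = "t_air_c")
    q10s <- fit_stage_q10(opaque, env, stage_windows(cfg), temp_var = tv)
    readr::write_csv(q10s, p("q10_fits.csv"), progress = FALSE)
    pairs <- pair_cycle(fx, flux_col = if ("flux_corrected" %in% names(fx))
      "flux_corrected" else "flux")
    gpp <- partition_gpp(pairs, drop_unpaired = TRUE)
    readr::write_csv(gpp, p("gpp.csv"), progress = FALSE)
    out$q10_fits <- q10s
    out$gpp <- gpp
    counts$q10_fits <- nrow(q10s)
  }

  if ("budget" %in% stages) {
    if (is.null(out$fluxes_corrected)) {
      need("fluxes_corrected.csv", "budget")
      out$fluxes_corrected <- read_fluxes(p("fluxes_corrected.csv"))
    }
    need("doc.csv", "budget")
    need("inventory.csv", "budget")
    doc <- read_doc(p("doc.csv"))
    inventory <- read_inventory(p("inventory.csv"))
    budgets <- pipeline_budgets(out$fluxes_corrected, doc, inventory, cfg)
    write_budgets(budgets, p("budgets.csv"))
    grp <- if ("treatment" %in% names(budgets) &&
               all(table(budgets$treatment) >= 2)) "treatment" else NULL
    cmp <- compare_balances(budgets, group = grp)
    writeLines(format_comparison(cmp), p("comparison.txt"))
    out$budgets <- budgets
    out$comparison <- cmp
    counts$budgets <- nrow(budgets)
  }

  if ("validate" %in% stages) {
    if (is.null(out$budgets)) {
      need("budgets.csv", "validate")
      out$budgets <- read_budgets(p("budgets.csv"))
    }
    b <- out$budgets
    resid <- b$flux_balance - b$stock_balance
    tol <- if (!is.null(closure_tol_g)) closure_tol_g else {
      s <- stats::sd(resid)
      if (is.na(s) || s < 1e-9) 1e-6 else 2 * sqrt(stats::sd(b$flux_balance)^2 +
                                                     stats::sd(b$stock_balance)^2)
    }
    pass <- abs(resid) <= tol
    val <- tibble::tibble(collar_id = b$collar_id, residual_g_c = resid,
                          tolerance_g_c = tol, pass = pass)
    readr::write_csv(val, p("validation.csv"), progress = FALSE)
    out$validation <- val
    if (!all(pass)) {
      warning("closure validation failed for collar(s): ",
              paste(b$collar_id[!pass], collapse = ", "), call. = FALSE)
    }
  }

  manifest <- c(
    sprintf("config_hash: %s", config_hash(cfg)),
    sprintf("rng_seed: %d", cfg$rng_seed),
    sprintf("stages: %s", paste(stages, collapse = ",")),
    vapply(names(counts), function(nm) sprintf("rows_%s: %d", nm,
                                               counts[[nm]]), character(1))
  )
  writeLines(manifest, p("manifest.txt"))
  out$manifest <- manifest
  invisible(out)
}

#' Semantic hash of a configuration
#'
#' Changes iff any configuration value changes; used in the run manifest.
#'
#' @param cfg A `sim_config`.
#' @return A character hash.
#' @export
config_hash <- function(cfg) {
  plain <- lapply(unclass(cfg), function(x) {
    if (inherits(x, "Date")) as.character(x) else x
  })
  rlang::hash(plain)
}

#' Assemble budgets from flux records the way the pipeline does
#'
#' Builds the hourly NEE series for each collar (the transparent, corrected
#' flux where present, else the opaque flux — during the pre-sowing
#' soil-only period NEE equals Reco) and hands it to [carbon_budgets()].
#'
#' @param fluxes Flux records (with `flux_corrected` if the correction stage
#'   ran).
#' @param doc DOC events.
#' @param inventory Stock inventory.
#' @param cfg A [sim_config()] providing the collar area and period.
#' @return See [carbon_budgets()].
#' @export
pipeline_budgets <- function(fluxes, doc, inventory, cfg) {
  flux_col <- if ("flux_corrected" %in% names(fluxes)) "flux_corrected" else
    "flux"
  pairs <- pair_cycle(fluxes, flux_col = flux_col)
  nee_hourly <- pairs |>
    dplyr::mutate(nee = ifelse(is.na(.data$nee), .data$reco, .data$nee)) |>
    dplyr::select("collar_id", "hour", "nee")
  period <- as.POSIXct(paste(c(cfg$start_date, cfg$end_date),
                             c("00:00:00", "23:00:00")), tz = "UTC")
  carbon_budgets(nee_hourly, doc, inventory, cfg$collar_area,
                 period = period)
}

format_comparison <- function(cmp) {
  lines <- c("flux-based vs stock-based carbon balances (g C per mesocosm)",
             "")
  if (!is.null(cmp$group_summary)) {
    lines <- c(lines, "group means +/- sd:",
               utils::capture.output(as.data.frame(cmp$group_summary)), "")
  }
  lines <- c(lines,
             sprintf("paired mean difference: %.4f +/- %.4f g C (t = %.3f, df = %s, p = %.3f)",
                     cmp$paired$mean_difference, cmp$paired$sd_difference,
                     cmp$paired$t, format(cmp$paired$df), cmp$paired$p_value),
             sprintf("RMSE about the 1:1 line: %.4f g C", cmp$rmse_1to1),
             sprintf("flux ~ stock OLS: slope %.3f, intercept %.4f, r2 %.3f",
                     cmp$fit$slope, cmp$fit$intercept, cmp$fit$r2))
  if (!is.null(cmp$anova)) {
    lines <- c(lines, "",
               sprintf("one-way ANOVA across treatments (flux): F = %.3f (df %d, %d), p = %.3f",
                       cmp$anova$flux$F, cmp$anova$flux$df_between,
                       cmp$anova$flux$df_within, cmp$anova$flux$p_value),
               sprintf("one-way ANOVA across treatments (stock): F = %.3f (df %d, %d), p = %.3f",
                       cmp$anova$stock$F, cmp$anova$stock$df_between,
                       cmp$anova$stock$df_within, cmp$anova$stock$p_value))
  }
  lines
}
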