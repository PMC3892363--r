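#' Generate drainage / DOC collection events
#'
#' Rainfall percolates through each collar and accumulates in its buried
#' collection bottle; a collection event occurs when rain stops and at least
#' `doc_collect_threshold_l` has accumulated, plus a final collection at the
#' end of the run. Each wet hour contributes
#' `rain_mm_per_h * collar_area` litres (1 mm over 1 m^2 = 1 L) times the
#' drainage-collection efficiency. Event concentrations are drawn around
#' `doc_conc`; exactly `doc_conc` when `doc_conc_sd` is zero.
#'
#' @param cfg A [sim_config()].
#' @param env Environment series from [generate_environment()] (supplies the
#'   rain flags).
#' @return A tibble with one row per collar x event: `collar_id`, `date`,
#'   `volume_l` (collected), `conc_mg_l`. Zero rows if it never rains.
#' @export
generate_doc_events <- function(cfg, env) {
  validate_sim_config(cfg)
  rain <- env$rain
  if (!any(rain)) {
    return(tibble::tibble(collar_id = integer(), date = as.Date(character()),
                          volume_l = numeric(), conc_mg_l = numeric()))
  }
  # bottle receives the collected fraction of drainage; mm over m^2 = L
  collected_per_hour_l <- cfg$rain_mm_per_h * cfg$collar_area *
    cfg$doc_collection_efficiency
  n <- length(rain)
  acc <- 0
  events <- list()
  for (i in seq_len(n)) {
    if (rain[i]) acc <- acc + collected_per_hour_l
    end_of_spell <- rain[i] && (i == n || !rain[i + 1])
    if ((end_of_spell && acc >= cfg$doc_collect_threshold_l) ||
        (i == n && acc > 0)) {
      events[[length(events) + 1]] <-
        list(date = as.Date(env$timestamp[i], tz = "UTC"), volume_l = acc)
      acc <- 0
    }
  }
  ev <- dplyr::bind_rows(lapply(events, tibble::as_tibble))
  out <- lapply(seq_len(cfg$n_collars), function(k) {
    conc <- with_collar_seed(cfg$rng_seed, 10000L + k, {
      if (cfg$doc_conc_sd > 0) {
        pmax(0.1, stats::rnorm(nrow(ev), cfg$doc_conc, cfg$doc_conc_sd))
      } else rep(cfg$doc_conc, nrow(ev))
    })
    tibble::tibble(collar_id = k, date = ev$date, volume_l = ev$volume_l,
                   conc_mg_l = conc)
  })
  dplyr::bind_rows(out)
}
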