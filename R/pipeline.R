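config_error <- function(...) {
  stop(structure(class = c("whaletrack_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the whole analysis pipeline
#'
#' Orchestrates simulate -> fit -> classify -> metrics -> residency ->
#' diel from a single YAML (or list) configuration, writing each stage's
#' outputs and a run manifest to the output directory. Stages are
#' deterministic given identical inputs and seeds, so a rerun with the
#' same configuration reproduces the classification byte for byte.
#'
#' Configuration keys: `seed`; `simulate` (either `preset` or the
#' arguments of [sim_config()]); `fit` (`dt_hours`, `mcmc` with `chains`,
#' `iterations`, `burn_in`, `thin`); optional `input` (an Argos CSV to use
#' instead of simulating); `stages` (subset of the stage names, default
#' all).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; side effect: `tracks.csv`, `truth.csv`,
#'   `states.csv`, `kinematics.csv`, `residency.json`, `diel.json`,
#'   `manifest.json` as applicable.
#' @export
run_pipeline <- function(config, out_dir) {
  t_start <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a YAML map")
  if (is.null(config$seed)) config_error("config field 'seed' is required")
  seed <- as.integer(config$seed)
  stages <- config$stages %||% c("simulate", "fit", "classify", "metrics",
                                 "residency", "diel")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, config = config, stages = list(),
                   version = as.character(utils::packageVersion("whaletrack")))
  status <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  tracks <- NULL; truth <- NULL
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) config_error("input file not found: ", config$input)
    tracks <- read_argos_observations(config$input, quiet = TRUE)
    status("input", length(tracks), " track(s) read from ", config$input)
  } else if ("simulate" %in% stages) {
    sc <- config$simulate %||% list()
    cfg <- do.call(sim_config, c(sc, list(seed = seed)))
    truth <- simulate_tracks(cfg)
    tracks <- observe_tracks(truth, cfg)
    write_argos_observations(tracks, file.path(out_dir, "tracks.csv"))
    ts <- truth_states(truth)
    write_states(ts, file.path(out_dir, "truth.csv"), "csv")
    status("simulate", length(tracks), " track(s), seed ", seed)
    manifest$stages$simulate <- list(n_tracks = length(tracks), seed = seed)
  }
  if (is.null(tracks)) config_error("no input: provide 'input' or keep the simulate stage")

  states <- NULL
  if (any(c("fit", "classify") %in% stages)) {
    fc <- config$fit %||% list()
    dt_hours <- fc$dt_hours %||% 2
    mc <- fc$mcmc %||% list()
    mcmc <- list(n_chains = mc$chains %||% 2, n_iter = mc$iterations %||% 50000,
                 burn_in = mc$burn_in %||% 45000, thin = mc$thin %||% 5)
    em <- if (is.null(fc$error_model)) argos_error_model() else argos_error_model(fc$error_model)
    fit <- fit_hssm(tracks, dt_hours, em, mcmc, seed = seed)
    states <- classify_behaviour(fit)
    write_states(states, file.path(out_dir, "states.csv"), "csv")
    status("fit", nrow(states), " states, ", mcmc$n_chains, " chain(s)")
    manifest$stages$fit <- c(mcmc, list(dt_hours = dt_hours,
                                        n_states = nrow(states),
                                        rhat_max = if (mcmc$n_chains >= 2)
                                          max(gelman_rubin(fit)) else NA))
  }

  kin <- NULL
  if ("metrics" %in% stages && !is.null(states)) {
    kin <- speed_series(states)
    out <- kin
    out$t_start <- format(out$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    out$t_end <- format(out$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(out, file.path(out_dir, "kinematics.csv"), row.names = FALSE)
    status("metrics", nrow(kin), " intervals")
    manifest$stages$metrics <- list(n_intervals = nrow(kin))
  }

  if ("residency" %in% stages && !is.null(kin)) {
    res <- tryCatch({
      thr <- median_ars_speed(kin)
      recs <- residency_records(kin, thr)
      km <- kaplan_meier(recs)
      areas <- extract_ars_areas(states)
      list(threshold_kmh = thr,
           records = recs,
           km = km[c("time", "surv", "median", "q25", "q75",
                     "n_events", "n_censored")],
           ars_areas = lapply(areas, function(a)
             a[c("animal_id", "area_km2", "duration_h", "n_positions", "centroid")]),
           budget = behaviour_time_budget(states))
    }, error = function(e) list(error = conditionMessage(e)))
    if (is.null(res$error)) {
      res$records$tagging_date <- as.character(res$records$tagging_date)
    }
    jsonlite::write_json(res, file.path(out_dir, "residency.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    status("residency", if (is.null(res$error)) paste0(nrow(res$records), " records")
           else paste0("skipped: ", res$error))
    manifest$stages$residency <- list(ok = is.null(res$error))
  }

  if ("diel" %in% stages && !is.null(kin)) {
    diel <- tryCatch({
      hrs <- solar_hour(kin$t_start, states$lon[match(kin$t_start, states$time)])
      transit <- kin$class == "transiting"
      list(
        transit_speed = if (sum(transit) >= 8)
          unclass(diel_profile(hrs[transit], kin$speed_kmh[transit])) else NULL,
        ars_probability = unclass(hourly_ars_probability(states))
      )
    }, error = function(e) list(error = conditionMessage(e)))
    jsonlite::write_json(diel, file.path(out_dir, "diel.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    status("diel", if (is.null(diel$error)) "profiles written"
           else paste0("skipped: ", diel$error))
    manifest$stages$diel <- list(ok = is.null(diel$error))
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
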