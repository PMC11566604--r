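#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (optional) -> preprocess -> behavior -> detect ->
#' event metrics -> connectivity -> prediction -> report. Every stage logs
#' one structured line; outputs are written under `outdir` and listed in the
#' returned manifest. Given the same configuration (including seeds) the run
#' is deterministic.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' optional sections:
#' \describe{
#'   \item{simulate}{arguments for [sim_config()], or `preset:
#'     movement|footshock|connectivity` with overrides. If absent, `traces`
#'     must point to a CSV readable by [read_traces_csv()].}
#'   \item{preprocess}{`window_s` (baseline window, default 90).}
#'   \item{behavior}{[segment_states()] thresholds.}
#'   \item{detect}{[detect_transients()] thresholds.}
#'   \item{metrics}{`pre_s`, `post_s` and [response_metrics()] settings.}
#'   \item{connectivity}{`max_lag_s`, `min_samples`.}
#'   \item{predict}{`lags_s`, `n_folds`, `num_trees`.}
#' }
#' Stages without the inputs they need (e.g. connectivity with a single
#' region) are skipped with a log line.
#'
#' @param config Path to a YAML file or a nested list.
#' @param outdir Output directory (created if missing).
#' @param seed Overrides the config seed when not `NULL`.
#' @return A list of class `"fp_report"`: `manifest` (tibble of written
#'   files), `summaries` (named list of tibbles), `metadata` (config hash,
#'   seed, package version). No multiple-testing correction is applied
#'   anywhere, and the report metadata says so.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  assert_that(is.list(cfg), "config must be a YAML path or a list")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  summaries <- list()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    if (grepl("\\.csv$", name)) readr::write_csv(x, path) else
      write_json_summary(x, path)
    files <<- c(files, path)
    path
  }

  # --- simulate or load -----------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    preset <- sc$preset %||% "custom"
    args <- sc[setdiff(names(sc), "preset")]
    if (!is.null(seed)) args$seed <- seed
    sim_cfg <- switch(preset,
      movement = do.call(sim_movement_config, args),
      footshock = do.call(sim_footshock_config, args),
      connectivity = do.call(sim_connectivity_config, args),
      custom = do.call(sim_config, args))
    sim <- simulate_recording(sim_cfg)
    traces <- sim$traces
    rate <- sim$rate_hz
    behavior <- sim$behavior
    stimuli <- sim$stimuli
    log_stage("simulate", "preset=%s regions=%s duration=%gs seed=%d",
              preset, paste(sim_cfg$regions, collapse = ","),
              sim_cfg$duration_s, sim_cfg$seed)
    emit(sim$ground_truth$events, "ground_truth_events.csv")
  } else if (!is.null(cfg$traces)) {
    assert_that(file.exists(cfg$traces),
                sprintf("stage 'load': trace file not found: %s", cfg$traces))
    traces <- read_traces_csv(cfg$traces)
    rate <- cfg$rate_hz %||% 30
    behavior <- NULL
    stimuli <- NULL
    log_stage("load", "traces=%s rows=%d", cfg$traces, nrow(traces))
  } else {
    stop("stage 'input': config needs either a 'simulate' section or 'traces'",
         call. = FALSE)
  }

  # --- preprocess -----------------------------------------------------------
  window_s <- cfg$preprocess$window_s %||% 90
  proc <- process_traces(traces, rate, window_s = window_s)
  log_stage("preprocess", "window=%gs channels=%d rows=%d", window_s,
            dplyr::n_distinct(paste(proc$region, proc$channel)), nrow(proc))
  emit(proc, "processed_traces.csv")

  # --- behavior -------------------------------------------------------------
  states <- NULL
  if (!is.null(behavior)) {
    bv <- cfg$behavior %||% list()
    states <- segment_states(behavior$movement$index, rate,
                             theta_move = bv$theta_move %||% 0.05,
                             min_move_s = bv$min_move_s %||% 1,
                             min_quiescence_s = bv$min_quiescence_s %||% 3,
                             bridge_s = bv$bridge_s %||% 0.5)
    log_stage("behavior", "segments=%d onsets=%d", nrow(states$segments),
              length(states$onsets))
    emit(states$segments, "state_segments.csv")
  } else {
    log_stage("behavior", "skipped: no behavior stream")
  }

  # --- detect ---------------------------------------------------------------
  dt <- cfg$detect %||% list()
  det <- proc |>
    dplyr::group_by(.data$region, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      detect_transients(d$z, rate,
                        theta_on = dt$theta_on %||% 2,
                        theta_off = dt$theta_off %||% 0.5,
                        min_dur_s = dt$min_dur_s %||% 1,
                        merge_gap_s = dt$merge_gap_s %||% 0.5)
    }) |>
    dplyr::ungroup()
  log_stage("detect", "events=%d", nrow(det))
  emit(det, "transients.csv")
  dur_summary <- det |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n = dplyr::n(),
                     frequency_per_min = dplyr::n() / (max(proc$time_s) / 60),
                     mean_duration_s = mean(.data$duration_s),
                     fraction_over_20s = mean(.data$duration_s > 20))
  summaries$transients <- dur_summary
  emit(dur_summary, "transient_summary.csv")

  # --- event-aligned metrics ------------------------------------------------
  event_times <- if (!is.null(stimuli)) stimuli$onset_s else
    if (!is.null(states)) states$onsets else numeric()
  mx <- cfg$metrics %||% list()
  if (length(event_times) >= 2) {
    pre_s <- mx$pre_s %||% 5
    post_s <- mx$post_s %||% if (!is.null(stimuli)) 20 else 40
    per_region <- split(proc, proc$region)
    met_rows <- list()
    for (region in names(per_region)) {
      d <- per_region[[region]]
      za <- d$z[d$channel == "astro"]
      zn <- d$z[d$channel == "neuron"]
      if (!length(za) || !length(zn)) next
      ens_a <- build_ensemble(za, event_times, rate, pre_s, post_s)
      ens_n <- build_ensemble(zn, event_times, rate, pre_s, post_s)
      rm_a <- response_metrics(ens_a, "astro")
      rm_n <- response_metrics(ens_n, "neuron")
      pd <- paired_differences(rm_a, rm_n)
      met_rows[[region]] <- dplyr::bind_rows(
        dplyr::mutate(rm_a$summary, region = region, cell_type = "astro"),
        dplyr::mutate(rm_n$summary, region = region, cell_type = "neuron"),
        dplyr::mutate(pd$summary, region = region, cell_type = "paired"))
    }
    if (length(met_rows)) {
      metrics_tbl <- dplyr::bind_rows(met_rows)
      summaries$response_metrics <- metrics_tbl
      emit(metrics_tbl, "response_metrics.csv")
      log_stage("metrics", "events=%d regions=%d", length(event_times),
                length(met_rows))
    }
  } else {
    log_stage("metrics", "skipped: fewer than 2 alignment events")
  }

  # --- connectivity ---------------------------------------------------------
  cn <- cfg$connectivity %||% list()
  regions <- unique(proc$region)
  if (length(regions) >= 2 && !is.null(states)) {
    conn_rows <- list()
    for (ct in c("astro", "neuron")) {
      sub <- proc[proc$channel == ct, c("time_s", "region", "z")]
      for (st in c("stationary", "movement")) {
        res <- tryCatch(
          state_conditioned_series(sub, states, st,
                                   min_samples = cn$min_samples %||% 300),
          error = function(e) NULL)
        if (is.null(res)) next
        cm <- interregion_spearman(res, state = st, cell_type = ct)
        conn_rows[[paste(ct, st)]] <- tidy(cm)
        emit(tibble::as_tibble(cm$r, rownames = "region"),
             sprintf("connectivity_%s_%s.csv", ct, st))
      }
    }
    if (length(conn_rows)) {
      conn_tbl <- dplyr::bind_rows(conn_rows)
      summaries$connectivity <- conn_tbl
      log_stage("connect", "matrices=%d", length(conn_rows))
    }
  } else {
    log_stage("connect", "skipped: needs >= 2 regions and behavior states")
  }

  # --- prediction -----------------------------------------------------------
  pd_cfg <- cfg$predict %||% list()
  pred_rows <- list()
  for (region in regions) {
    d <- proc[proc$region == region, ]
    za <- d$z[d$channel == "astro"]
    zn <- d$z[d$channel == "neuron"]
    if (!length(za) || !length(zn)) next
    feats <- build_lagged_features(zn, pd_cfg$lags_s %||% 0:10, rate)
    fit <- fit_variance_explained(feats, za,
                                  n_folds = pd_cfg$n_folds %||% 5,
                                  num_trees = pd_cfg$num_trees %||% 100,
                                  seed = seed %||% cfg$seed %||% 1,
                                  region = region, state = "session")
    pred_rows[[region]] <- glance(fit)
  }
  if (length(pred_rows)) {
    pred_tbl <- dplyr::bind_rows(pred_rows)
    summaries$prediction <- pred_tbl
    emit(pred_tbl, "prediction.csv")
    log_stage("predict", "regions=%d", length(pred_rows))
  }

  # --- report ---------------------------------------------------------------
  metadata <- list(config_hash = rlang::hash(cfg),
                   seed = seed %||% cfg$seed %||% 1,
                   package_version = as.character(utils::packageVersion("glianet")),
                   multiple_testing_correction = "none")
  report <- list(metadata = metadata,
                 summaries = lapply(summaries, as.data.frame))
  emit(report, "report.json")
  manifest <- tibble::tibble(file = files, exists = file.exists(files))
  log_stage("report", "files=%d", nrow(manifest))
  structure(list(manifest = manifest, summaries = summaries,
                 metadata = metadata),
            class = "fp_report")
}
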