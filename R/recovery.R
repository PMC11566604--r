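#' Parameter-recovery experiment: simulate, preprocess, measure kinetics
#'
#' Runs the full validation loop for one stimulus condition: generate a
#' synthetic session (or several) whose generator kinetics are the
#' configured defaults, preprocess the raw traces, align on the behavioral
#' events (recovered movement onsets, or the footshock train), and read the
#' kinetic parameters back out with [response_metrics()] and
#' [paired_differences()]. Comparing the recovered means against the
#' configured values validates the whole detection/measurement chain.
#'
#' The movement condition runs one long free-behavior session with
#' `n_trials` well-separated bouts ([sim_movement_config()]); movement
#' onsets are re-derived from the movement index via [segment_states()], not
#' taken from ground truth. The footshock condition runs
#' `ceiling(n_trials / 4)` sessions of four shocks each
#' ([sim_footshock_config()]) with consecutive seeds, mirroring a
#' five-animal, four-trial design.
#'
#' @param condition `"movement"` or `"footshock"`.
#' @param n_trials Total trials to collect (default 20).
#' @param seed Base integer seed.
#' @return A list of class `"fp_recovery"`: `astro`, `neuron`
#'   (`"fp_metrics"` trial tables pooled across sessions), `paired`
#'   (`"fp_paired"`), `condition`, `n_trials`, `config` (the first session's
#'   config).
#' @export
recover_event_kinetics <- function(condition = c("movement", "footshock"),
                                   n_trials = 20, seed = 1L) {
  condition <- match.arg(condition)
  if (condition == "movement") {
    cfg <- sim_movement_config(n_trials = n_trials, seed = seed)
    sessions <- list(simulate_recording(cfg))
    post_s <- 45
  } else {
    n_sessions <- ceiling(n_trials / 4)
    sessions <- lapply(seq_len(n_sessions), function(i) {
      simulate_recording(sim_footshock_config(n_trials = 4, seed = seed + i - 1L))
    })
    cfg <- sessions[[1]]$config
    post_s <- 20
  }
  a_rows <- n_rows <- list()
  for (sim in sessions) {
    proc <- process_traces(sim$traces, sim$rate_hz)
    events <- if (condition == "movement") {
      segment_states(sim$behavior$movement$index, sim$rate_hz)$onsets
    } else {
      sim$stimuli$onset_s
    }
    za <- proc$z[proc$channel == "astro"]
    zn <- proc$z[proc$channel == "neuron"]
    ea <- build_ensemble(za, events, sim$rate_hz, pre_s = 5, post_s = post_s)
    en <- build_ensemble(zn, events, sim$rate_hz, pre_s = 5, post_s = post_s)
    a_rows[[length(a_rows) + 1L]] <- response_metrics(ea, "astro")$trials
    n_rows[[length(n_rows) + 1L]] <- response_metrics(en, "neuron")$trials
  }
  astro <- dplyr::bind_rows(a_rows)[seq_len(min(n_trials, sum(vapply(a_rows, nrow, 1L)))), ]
  neuron <- dplyr::bind_rows(n_rows)[seq_len(nrow(astro)), ]
  astro$trial <- seq_len(nrow(astro))
  neuron$trial <- seq_len(nrow(neuron))
  astro_m <- structure(list(trials = astro, summary = metrics_summary(astro),
                            cell_type = "astro"), class = "fp_metrics")
  neuron_m <- structure(list(trials = neuron, summary = metrics_summary(neuron),
                             cell_type = "neuron"), class = "fp_metrics")
  structure(list(astro = astro_m, neuron = neuron_m,
                 paired = paired_differences(astro_m, neuron_m),
                 condition = condition, n_trials = nrow(astro), config = cfg),
            class = "fp_recovery")
}

#' Mean of one recovered metric over responding trials
#'
#' @param recovery An `"fp_recovery"` object.
#' @param cell_type `"astro"` or `"neuron"`.
#' @param metric Column of the trial table (e.g. `"latency_s"`).
#' @return Mean over responders, NA values removed.
#' @export
recovered_mean <- function(recovery, cell_type, metric) {
  tr <- recovery[[cell_type]]$trials
  v <- tr[[metric]][tr$responder]
  mean(v, na.rm = TRUE)
}
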