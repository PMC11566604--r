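#' Simulation configuration for synthetic dual-color photometry recordings
#'
#' Builds the configuration object consumed by [make_behavior()],
#' [make_stimulus_train()] and [simulate_recording()]. Defaults encode the
#' study conditions the analysis is calibrated against: 30 Hz sampling,
#' recordings from S1/M1/CA1, movement-evoked astrocytic transients with
#' ~2.47 s onset latency and ~5.66 s peak time versus ~0.42 s / ~1.07 s in
#' neurons, an astrocytic peak that precedes a neuronal calcium valley by
#' ~1.5 s, astrocytic transient durations mostly above 20 s versus mostly
#' below 20 s in neurons, stationary-state astrocytic microdomain events at
#' roughly one tenth of the movement-state amplitude, and inter-regional
#' shared drive that is much stronger during movement (r ~ 0.85) than during
#' stationary behavior (r ~ 0.3).
#'
#' @param duration_s Recording length in seconds (>= 60).
#' @param rate_hz Sampling rate in samples per second.
#' @param regions Character vector of region labels. Coordinates for the graph
#'   layout are taken from [region_coordinates()] when available.
#' @param neuron_kinetics,astro_kinetics Lists with elements
#'   `onset_latency_s` (time from the triggering behavioral event to signal
#'   onset), `peak_time_s` (trigger to peak), `duration_s` and `duration_sd_s`
#'   (signal onset to return to baseline; per-event draws are normal,
#'   truncated below), and `amplitude_z` (event amplitude in latent signal
#'   units). `peak_time_s` must exceed `onset_latency_s` and `duration_s` must
#'   exceed `peak_time_s - onset_latency_s`.
#' @param valley_offset_s Seconds between an astrocytic peak and the induced
#'   neuronal valley (positive: valley follows the peak).
#' @param valley_depth_z Depth of the subtractive neuronal dip.
#' @param valley_width_s Gaussian sd of the dip, in seconds.
#' @param movement_bouts List: `rate_per_min`, `duration_mean_s`,
#'   `duration_sd_s`, `min_quiescence_s`. `rate_per_min = 0` disables bouts.
#' @param microdomain List: `rate_per_min`, `amplitude_fraction`,
#'   `duration_mean_s`, `duration_sd_s`. Stationary-state astrocytic events at
#'   `amplitude_fraction` of the movement-evoked amplitude.
#' @param coupling List: `movement`, `stationary` (shared-drive correlation by
#'   state), `drive_sd`, `noise_sd` (latent-signal units).
#' @param bleach List: `amplitude_fraction`, `tau_s`; single-exponential
#'   photobleaching applied multiplicatively to raw fluorescence.
#' @param footshock `NULL`, or a list `amplitude_mA` (metadata only),
#'   `pulse_s`, `interval_s`, `n_trials`, `start_s`.
#' @param control_channels If `TRUE`, add event-free GFP/mCherry channels
#'   (noise and bleaching only).
#' @param f0 Baseline raw fluorescence (arbitrary units).
#' @param gain Fractional fluorescence change per latent signal unit.
#' @param amplitude_jitter_sd Log-normal sd of per-event amplitude jitter.
#' @param arena List: `size_cm`, `width_px`, `height_px` for behavior video.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [sim_movement_config()], [sim_footshock_config()],
#'   [sim_connectivity_config()] for condition presets.
#' @export
sim_config <- function(duration_s = 600,
                       rate_hz = 30,
                       regions = c("S1", "M1", "CA1"),
                       neuron_kinetics = list(onset_latency_s = 0.42,
                                              peak_time_s = 1.07,
                                              duration_s = 8,
                                              duration_sd_s = 2,
                                              amplitude_z = 6),
                       astro_kinetics = list(onset_latency_s = 2.47,
                                             peak_time_s = 5.66,
                                             duration_s = 35,
                                             duration_sd_s = 5,
                                             amplitude_z = 8),
                       valley_offset_s = 1.50,
                       valley_depth_z = 5,
                       valley_width_s = 0.3,
                       movement_bouts = list(rate_per_min = 0.3,
                                             duration_mean_s = 6,
                                             duration_sd_s = 2,
                                             min_quiescence_s = 3),
                       microdomain = list(rate_per_min = 0.3,
                                          amplitude_fraction = 0.1,
                                          duration_mean_s = 25,
                                          duration_sd_s = 5),
                       coupling = list(movement = 0.85,
                                       stationary = 0.3,
                                       drive_sd = 0.3,
                                       noise_sd = 0.25),
                       bleach = list(amplitude_fraction = 0.2, tau_s = 1200),
                       footshock = NULL,
                       control_channels = FALSE,
                       f0 = 100,
                       gain = 0.05,
                       amplitude_jitter_sd = 0.1,
                       arena = list(size_cm = 40, width_px = 160, height_px = 90),
                       seed = 1L) {
  cfg <- list(duration_s = duration_s, rate_hz = rate_hz, regions = regions,
              neuron_kinetics = neuron_kinetics, astro_kinetics = astro_kinetics,
              valley_offset_s = valley_offset_s, valley_depth_z = valley_depth_z,
              valley_width_s = valley_width_s, movement_bouts = movement_bouts,
              microdomain = microdomain, coupling = coupling, bleach = bleach,
              footshock = footshock, control_channels = control_channels,
              f0 = f0, gain = gain, amplitude_jitter_sd = amplitude_jitter_sd,
              arena = arena, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$duration_s >= 60, "duration_s must be at least 60 s")
  assert_that(cfg$rate_hz > 0, "rate_hz must be positive")
  assert_that(length(cfg$regions) >= 1, "at least one region is required")
  for (ct in c("astro_kinetics", "neuron_kinetics")) {
    k <- cfg[[ct]]
    assert_that(k$onset_latency_s >= 0, paste(ct, "onset_latency_s must be >= 0"))
    assert_that(k$peak_time_s > k$onset_latency_s,
                paste(ct, "peak_time_s must exceed onset_latency_s"))
    assert_that(k$duration_s > k$peak_time_s - k$onset_latency_s,
                paste(ct, "duration_s must exceed the rise time"))
    assert_that(k$amplitude_z >= 0, paste(ct, "amplitude_z must be >= 0"))
  }
  assert_that(cfg$valley_width_s > 0, "valley_width_s must be positive")
  assert_that(cfg$movement_bouts$rate_per_min >= 0,
              "movement_bouts rate_per_min must be >= 0")
  assert_that(cfg$movement_bouts$duration_mean_s > 0,
              "movement_bouts duration_mean_s must be positive")
  md <- cfg$microdomain
  assert_that(md$amplitude_fraction > 0 && md$amplitude_fraction <= 1,
              "microdomain amplitude_fraction must lie in (0, 1]")
  cp <- cfg$coupling
  assert_that(all(c(cp$movement, cp$stationary) >= 0) &&
                all(c(cp$movement, cp$stationary) <= 1),
              "coupling state values must lie in [0, 1]")
  assert_that(cfg$bleach$tau_s > 0, "bleach tau_s must be positive")
  if (!is.null(cfg$footshock)) {
    fs <- cfg$footshock
    assert_that(fs$n_trials >= 1, "footshock n_trials must be >= 1")
    assert_that(fs$interval_s > fs$pulse_s,
                "footshock interval_s must exceed pulse_s")
  }
  invisible(cfg)
}

#' Condition presets mirroring the study's recording designs
#'
#' `sim_movement_config()` sets up a single-region free-behavior session with
#' `n_trials` well-separated movement bouts (long quiescent gaps so the slow
#' astrocytic responses do not overlap), used for movement-evoked timing
#' recovery. `sim_footshock_config()` sets up a stationary session with a
#' 0.6 mA / 1 s footshock train delivered every 5 min (4 trials by default)
#' and the footshock response kinetics: astrocyte onset latency 1.05 s, peak
#' 1.67 s, duration 8.05 s; neuron 0.20 s, 0.99 s, 6.24 s; astro-peak to
#' neuron-valley interval 3.35 s. `sim_connectivity_config()` sets up a
#' three-region session with frequent bouts for state-conditioned
#' connectivity analysis.
#'
#' @param n_trials Number of movement bouts (movement preset) or footshock
#'   pulses (footshock preset).
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
sim_movement_config <- function(n_trials = 20, seed = 1L, ...) {
  # ~150 s per trial keeps the astrocytic event duty cycle near 0.25 so that
  # session-level z-scoring leaves movement responses well above threshold.
  sim_config(duration_s = 60 + n_trials * 150,
             regions = "M1",
             movement_bouts = list(rate_per_min = 0.4,
                                   duration_mean_s = 5,
                                   duration_sd_s = 0,
                                   min_quiescence_s = 90,
                                   quiescence_extra_mean_s = 55),
             microdomain = list(rate_per_min = 0, amplitude_fraction = 0.1,
                                duration_mean_s = 20, duration_sd_s = 5),
             seed = seed, ...)
}

#' @rdname sim_movement_config
#' @export
sim_footshock_config <- function(n_trials = 4, seed = 1L, ...) {
  sim_config(duration_s = 300 * (n_trials + 1),
             regions = "S1",
             neuron_kinetics = list(onset_latency_s = 0.20,
                                    peak_time_s = 0.99,
                                    duration_s = 6.24,
                                    duration_sd_s = 0.5,
                                    amplitude_z = 6),
             astro_kinetics = list(onset_latency_s = 1.05,
                                   peak_time_s = 1.67,
                                   duration_s = 8.05,
                                   duration_sd_s = 0.5,
                                   amplitude_z = 8),
             valley_offset_s = 3.35,
             movement_bouts = list(rate_per_min = 0,
                                   duration_mean_s = 6,
                                   duration_sd_s = 2,
                                   min_quiescence_s = 3),
             microdomain = list(rate_per_min = 0, amplitude_fraction = 0.1,
                                duration_mean_s = 20, duration_sd_s = 5),
             footshock = list(amplitude_mA = 0.6, pulse_s = 1,
                              interval_s = 300, n_trials = n_trials,
                              start_s = 300),
             seed = seed, ...)
}

#' @rdname sim_movement_config
#' @export
sim_connectivity_config <- function(seed = 1L, duration_s = 300, ...) {
  sim_config(duration_s = duration_s,
             regions = c("S1", "M1", "CA1"),
             movement_bouts = list(rate_per_min = 2,
                                   duration_mean_s = 6,
                                   duration_sd_s = 2,
                                   min_quiescence_s = 3),
             seed = seed, ...)
}

#' Stereotaxic node coordinates for the recorded regions
#'
#' Anterior-posterior and mediolateral coordinates (mm from bregma) of the
#' fiber targets, used as node positions in connectivity graphs.
#'
#' @return A tibble with columns `region`, `ap_mm`, `ml_mm`.
#' @export
region_coordinates <- function() {
  tibble::tibble(region = c("S1", "M1", "CA1"),
                 ap_mm = c(-0.5, 0, -2.1),
                 ml_mm = c(-1.9, 1.0, 1.55))
}
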