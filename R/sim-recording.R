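#' Calcium transient kernel with exact onset, peak and end times
#'
#' Builds the event waveform used by [simulate_recording()]. The kernel spans
#' `[0, onset_latency_s + duration_s]` relative to the triggering behavioral
#' event: it is zero until `onset_latency_s`, rises to `amplitude_z` exactly
#' at `peak_time_s`, and returns to zero at `onset_latency_s + duration_s`.
#' Rise and decay are warped inverse-smoothstep segments, which are steep at
#' the onset, the peak and the termination; the configured latency, peak time
#' and duration are therefore recoverable by threshold- or fraction-of-peak
#' measurements regardless of the normalization scale applied downstream.
#'
#' @param kinetics Kinetics list (see [sim_config()]): `onset_latency_s`,
#'   `peak_time_s`, `duration_s`, `amplitude_z`.
#' @param rate_hz Sampling rate.
#' @param duration_s Optional override of `kinetics$duration_s` (used for
#'   per-event duration draws).
#' @return Numeric waveform vector; `attr(., "time_s")` gives sample times
#'   relative to the triggering event.
#' @export
transient_kernel <- function(kinetics, rate_hz, duration_s = NULL) {
  L <- kinetics$onset_latency_s
  P <- kinetics$peak_time_s
  D <- duration_s %||% kinetics$duration_s
  A <- kinetics$amplitude_z
  assert_that(L >= 0 && P > L && D > P - L, "kernel requires 0 <= onset < peak < end")
  assert_that(rate_hz > 0, "rate_hz must be positive")
  E <- L + D
  t <- seq(0, E, by = 1 / rate_hz)
  v <- numeric(length(t))
  rise <- t >= L & t <= P
  fall <- t > P & t <= E
  v[rise] <- sqrt(smoothstep_inv((t[rise] - L) / (P - L)))
  v[fall] <- 1 - smoothstep_inv((t[fall] - P) / (E - P))
  # the sampling grid rarely lands exactly on the peak; renormalize so the
  # sampled maximum equals the configured amplitude
  if (A > 0 && max(v) > 0) v <- v / max(v)
  out <- A * v
  attr(out, "time_s") <- t
  out
}

#' Simulate a multi-region dual-color photometry recording
#'
#' Generates raw fluorescence traces for astrocyte (470 nm) and neuron
#' (560 nm) channels in every configured region, with full ground-truth
#' annotation. The latent signal per channel is
#' `events + shared drive + white noise`; raw fluorescence is
#' `f0 * (1 + gain * signal) * bleach(t)`.
#'
#' Event structure:
#' * every movement onset and every footshock triggers one astrocytic and one
#'   neuronal transient per region, at the configured cell-type kinetics;
#' * each astrocytic peak induces a Gaussian dip (the neuronal calcium
#'   valley) on the same region's neuron channel, centered
#'   `valley_offset_s` after the astrocytic peak;
#' * stationary periods carry astrocytic microdomain events at
#'   `microdomain$amplitude_fraction` of the movement-evoked amplitude, so
#'   the ground-truth movement/stationary amplitude ratio is
#'   `1 / amplitude_fraction` (10 by default);
#' * the shared drive is a smooth unit-variance process mixed into every
#'   astro/neuron channel with state-dependent weight, so inter-regional and
#'   astro-neuron correlations are higher during movement;
#' * optional GFP/mCherry control channels carry noise and bleaching only.
#'
#' @param config A [sim_config()] object.
#' @param behavior Optional [make_behavior()] result; generated from `config`
#'   when `NULL`.
#' @param stimuli Optional [make_stimulus_train()] result; generated when the
#'   config has a footshock block, otherwise omitted.
#' @return A list of class `"fp_sim"`: `traces` (long tibble `time_s`,
#'   `region`, `channel`, `cell_type`, `value`), `rate_hz`, `behavior`,
#'   `stimuli`, `ground_truth` (events/states/onsets/coupling), `config`.
#' @export
simulate_recording <- function(config, behavior = NULL, stimuli = NULL) {
  validate_sim_config(config)
  if (is.null(behavior)) behavior <- make_behavior(config)
  if (is.null(stimuli) && !is.null(config$footshock)) {
    stimuli <- make_stimulus_train(config)
  }
  rate <- config$rate_hz
  n <- nrow(behavior$movement)
  assert_that(abs(n - round(config$duration_s * rate)) <= 1,
              "behavior and config cover different time axes")
  if (!is.null(stimuli)) {
    assert_that(max(stimuli$onset_s) <= config$duration_s,
                "stimuli and config cover different time axes")
  }
  set.seed(config$seed + 202L)

  trigger_times <- sort(c(behavior$onsets,
                          if (!is.null(stimuli)) stimuli$onset_s))
  trigger_kind <- c(rep("movement", length(behavior$onsets)),
                    if (!is.null(stimuli)) rep("footshock", nrow(stimuli)))
  trigger_kind <- trigger_kind[order(c(behavior$onsets,
                                       if (!is.null(stimuli)) stimuli$onset_s))]

  state <- rep("stationary", n)
  for (i in seq_len(nrow(behavior$segments))) {
    if (behavior$segments$label[i] == "movement") {
      i0 <- time_to_sample(behavior$segments$start_s[i], rate)
      i1 <- min(n, round(behavior$segments$end_s[i] * rate))
      state[i0:i1] <- "movement"
    }
  }

  cp <- config$coupling
  g <- smooth_noise(n, 0.5 * rate)            # global drive, all channels
  cvec <- ifelse(state == "movement", cp$movement, cp$stationary)
  stat_idx <- which(state == "stationary")
  stationary_runs <- true_runs(state == "stationary")

  bleach <- (1 - config$bleach$amplitude_fraction) +
    config$bleach$amplitude_fraction *
      exp(-sample_to_time(seq_len(n), rate) / config$bleach$tau_s)

  traces <- list()
  events <- list()
  for (region in config$regions) {
    sig <- list(astro = numeric(n), neuron = numeric(n))
    astro_peaks <- numeric()

    for (ct in c("astro", "neuron")) {
      kin <- config[[paste0(ct, "_kinetics")]]
      for (j in seq_along(trigger_times)) {
        dur <- max(rnorm(1, kin$duration_s, kin$duration_sd_s %||% 0),
                   kin$peak_time_s - kin$onset_latency_s + 1)
        amp <- kin$amplitude_z * rlnorm(1, 0, config$amplitude_jitter_sd)
        k <- transient_kernel(modifyList(kin, list(amplitude_z = amp)),
                              rate, duration_s = dur)
        t0 <- trigger_times[j]
        sig[[ct]] <- add_at(sig[[ct]], k, time_to_sample(t0, rate))
        events[[length(events) + 1L]] <- tibble::tibble(
          region = region, cell_type = ct, trigger = trigger_kind[j],
          trigger_s = t0,
          onset_s = t0 + kin$onset_latency_s,
          peak_s = t0 + kin$peak_time_s,
          end_s = t0 + kin$onset_latency_s + dur,
          amplitude = amp)
        if (ct == "astro") astro_peaks <- c(astro_peaks, t0 + kin$peak_time_s)
      }
    }

    # microdomain astrocytic events during stationary periods
    md <- config$microdomain
    if (md$rate_per_min > 0 && length(stat_idx) > 0) {
      kin <- config$astro_kinetics
      n_md <- rpois(1, md$rate_per_min * length(stat_idx) / rate / 60)
      if (n_md > 0) {
        md_t <- sample_to_time(sample(stat_idx, n_md, replace = TRUE), rate)
        for (t0 in sort(md_t)) {
          dur <- max(rnorm(1, md$duration_mean_s, md$duration_sd_s %||% 0),
                     kin$peak_time_s - kin$onset_latency_s + 1)
          amp <- kin$amplitude_z * md$amplitude_fraction *
            rlnorm(1, 0, config$amplitude_jitter_sd)
          k <- transient_kernel(modifyList(kin, list(amplitude_z = amp)),
                                rate, duration_s = dur)
          sig$astro <- add_at(sig$astro, k, time_to_sample(t0, rate))
          events[[length(events) + 1L]] <- tibble::tibble(
            region = region, cell_type = "astro", trigger = "microdomain",
            trigger_s = t0, onset_s = t0 + kin$onset_latency_s,
            peak_s = t0 + kin$peak_time_s,
            end_s = t0 + kin$onset_latency_s + dur, amplitude = amp)
        }
      }
    }

    # neuronal valley: subtractive Gaussian dip after each astro peak
    tgrid <- sample_to_time(seq_len(n), rate)
    for (pk in astro_peaks) {
      ctr <- pk + config$valley_offset_s
      w <- config$valley_width_s
      lo <- max(1L, time_to_sample(ctr - 4 * w, rate))
      hi <- min(n, time_to_sample(ctr + 4 * w, rate))
      if (lo <= hi) {
        idx <- lo:hi
        sig$neuron[idx] <- sig$neuron[idx] -
          config$valley_depth_z * exp(-(tgrid[idx] - ctr)^2 / (2 * w^2))
      }
    }

    for (ct in c("astro", "neuron")) {
      h <- smooth_noise(n, 0.5 * rate)        # channel-private drive component
      drive <- cp$drive_sd * (sqrt(cvec) * g + sqrt(1 - cvec) * h)
      s <- sig[[ct]] + drive + rnorm(n, 0, cp$noise_sd)
      traces[[paste(region, ct, sep = ".")]] <- tibble::tibble(
        time_s = tgrid, region = region, channel = ct, cell_type = ct,
        value = config$f0 * (1 + config$gain * s) * bleach)
    }
    if (isTRUE(config$control_channels)) {
      for (ct in c("gfp", "mcherry")) {
        s <- rnorm(n, 0, cp$noise_sd)
        traces[[paste(region, ct, sep = ".")]] <- tibble::tibble(
          time_s = tgrid, region = region, channel = ct, cell_type = "control",
          value = config$f0 * (1 + config$gain * s) * bleach)
      }
    }
  }

  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(region = character(), cell_type = character(),
                   trigger = character(), trigger_s = numeric(),
                   onset_s = numeric(), peak_s = numeric(), end_s = numeric(),
                   amplitude = numeric())

  structure(list(
    traces = dplyr::bind_rows(traces),
    rate_hz = rate,
    behavior = behavior,
    stimuli = stimuli,
    ground_truth = list(
      events = events,
      states = behavior$segments,
      movement_onsets = behavior$onsets,
      coupling = c(movement = cp$movement, stationary = cp$stationary),
      drive = g),
    config = config
  ), class = "fp_sim")
}

# Add kernel k into x starting at (1-based) index i0, clipping at both ends.
add_at <- function(x, k, i0) {
  n <- length(x)
  j <- seq_along(k) + i0 - 1L
  keep <- j >= 1L & j <= n
  x[j[keep]] <- x[j[keep]] + k[keep]
  x
}
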