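#' Detect calcium transients on a z-scored trace
#'
#' An event is seeded by a run of `z >= theta_on` sustained for at least
#' `min_dur_s`; its boundaries are then extended backwards to the preceding
#' upward crossing of `theta_off` and forwards until `z` falls below
#' `theta_off`. Events separated by less than `merge_gap_s` are merged. The
#' peak is the global maximum within the event, earliest sample on ties.
#'
#' @param z z-scored trace (a warning, not an error, is raised if the input
#'   does not look normalized).
#' @param rate_hz Sampling rate.
#' @param theta_on Seed threshold (z units).
#' @param theta_off Boundary threshold (z units).
#' @param min_dur_s Minimum sustained seed duration.
#' @param merge_gap_s Events closer than this merge.
#' @return Tibble: `onset_s`, `peak_s`, `end_s`, `peak_z`, `duration_s`.
#'   Intervals are half-open `[onset_s, end_s)`.
#' @export
detect_transients <- function(z, rate_hz, theta_on = 2, theta_off = 0.5,
                              min_dur_s = 1, merge_gap_s = 0.5) {
  if (abs(mean(z)) > 0.5 || sd(z) < 0.5 || sd(z) > 2) {
    warning("input does not look z-normalized (|mean| > 0.5 or sd outside [0.5, 2])")
  }
  n <- length(z)
  empty <- tibble::tibble(onset_s = numeric(), peak_s = numeric(),
                          end_s = numeric(), peak_z = numeric(),
                          duration_s = numeric())
  seeds <- true_runs(z >= theta_on)
  seeds <- seeds[seeds[, "end"] - seeds[, "start"] + 1L >= min_dur_s * rate_hz, ,
                 drop = FALSE]
  if (nrow(seeds) == 0) return(empty)
  below <- z < theta_off
  onset <- end_ <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, "start"]
    b <- which(below[seq_len(s - 1L)])
    onset[i] <- if (length(b)) max(b) + 1L else 1L
    e <- seeds[i, "end"]
    a <- which(below[seq.int(e, n)])
    end_[i] <- if (length(a)) e + min(a) - 2L else n
  }
  ev <- unique(data.frame(onset = onset, end = end_))
  ev <- ev[order(ev$onset), , drop = FALSE]
  # merge overlapping or near-adjacent events
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      gap_s <- (ev$onset[i] - merged$end[last] - 1L) / rate_hz
      if (gap_s < merge_gap_s) {
        merged$end[last] <- max(merged$end[last], ev$end[i])
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
  }
  peak_idx <- mapply(function(s, e) s + which.max(z[s:e]) - 1L,
                     merged$onset, merged$end)
  tibble::tibble(onset_s = sample_to_time(merged$onset, rate_hz),
                 peak_s = sample_to_time(peak_idx, rate_hz),
                 end_s = merged$end / rate_hz,
                 peak_z = z[peak_idx],
                 duration_s = (merged$end - merged$onset + 1L) / rate_hz)
}

#' Summary statistics of detected transients
#'
#' @param events Tibble from [detect_transients()].
#' @param recording_duration_s Total recording time (> 0).
#' @param bin_width_s Histogram bin width; bins are anchored at 0 so an edge
#'   falls exactly at 20 s, the duration that separates typical astrocytic
#'   from typical neuronal transients.
#' @return List: `frequency_per_min`, `durations_s`, `fraction_over_20s`,
#'   `histogram` (tibble `bin_start_s`, `bin_end_s`, `count`), `n_events`.
#' @export
transient_stats <- function(events, recording_duration_s, bin_width_s = 5) {
  assert_that(recording_duration_s > 0, "recording duration must be positive")
  durs <- events$duration_s
  freq <- nrow(events) / (recording_duration_s / 60)
  if (length(durs) == 0) {
    hist_tbl <- tibble::tibble(bin_start_s = numeric(), bin_end_s = numeric(),
                               count = integer())
    return(list(frequency_per_min = 0, durations_s = numeric(),
                fraction_over_20s = NA_real_, histogram = hist_tbl,
                n_events = 0L))
  }
  edges <- seq(0, ceiling(max(durs) / bin_width_s) * bin_width_s, by = bin_width_s)
  counts <- tabulate(findInterval(durs, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  list(frequency_per_min = freq,
       durations_s = durs,
       fraction_over_20s = mean(durs > 20),
       histogram = tibble::tibble(bin_start_s = edges[-length(edges)],
                                  bin_end_s = edges[-1],
                                  count = counts),
       n_events = nrow(events))
}

#' Event-triggered ensemble of trace segments
#'
#' Cuts `[event - pre_s, event + post_s)` windows from a z-scored trace, one
#' row per event. Events whose window does not fit inside the recording are
#' dropped (and reported). Optionally re-baselines each trial by subtracting
#' its pre-window mean. Per-bin mean and SEM (sample sd / sqrt(n)) summarize
#' the ensemble.
#'
#' @param z z-scored trace.
#' @param event_times Alignment times in seconds (movement onsets, shocks...).
#' @param rate_hz Sampling rate.
#' @param pre_s,post_s Window extent around each event.
#' @param rebaseline Subtract the pre-window mean per trial.
#' @return A list of class `"fp_ensemble"`: `matrix` (trials x time),
#'   `time_s` (relative to the event), `event_times` (used), `dropped`
#'   (times), `mean`, `sem`, `pre_s`, `post_s`, `rate_hz`.
#' @export
build_ensemble <- function(z, event_times, rate_hz, pre_s = 5, post_s = 20,
                           rebaseline = TRUE) {
  n <- length(z)
  npre <- round(pre_s * rate_hz)
  npost <- round(post_s * rate_hz)
  i0 <- time_to_sample(event_times, rate_hz)
  ok <- (i0 - npre) >= 1L & (i0 + npost - 1L) <= n
  if (any(!ok)) {
    message(sprintf("dropping %d event(s) without a full window", sum(!ok)))
  }
  assert_that(any(ok), "no usable trials: every window falls outside the recording")
  used <- event_times[ok]
  mat <- t(vapply(i0[ok], function(i) z[(i - npre):(i + npost - 1L)],
                  numeric(npre + npost)))
  if (rebaseline && npre > 0) {
    mat <- mat - rowMeans(mat[, seq_len(npre), drop = FALSE])
  }
  mu <- colMeans(mat)
  sem <- if (nrow(mat) > 1) apply(mat, 2, sd) / sqrt(nrow(mat)) else
    rep(0, ncol(mat))
  structure(list(matrix = mat,
                 time_s = (seq_len(npre + npost) - npre - 1L) / rate_hz,
                 event_times = used, dropped = event_times[!ok],
                 mean = mu, sem = sem,
                 pre_s = pre_s, post_s = post_s, rate_hz = rate_hz,
                 rebaseline = rebaseline),
            class = "fp_ensemble")
}

#' Event-aligned response kinetics per trial
#'
#' For each ensemble trial, measures (on a lightly smoothed copy of the
#' trace, `smooth_s` moving mean):
#' * `peak_z`, `peak_time_s`: maximum and argmax within `(0, peak_window_s]`
#'   (earliest sample on ties);
#' * responder gate: trials whose `peak_z` stays below `theta_resp` are
#'   non-responders and excluded from summaries;
#' * `latency_s`: first crossing of `latency_frac * peak_z` sustained for
#'   `sustain_s`, searched within `(0, latency_window_s]`. The
#'   fraction-of-peak criterion makes onset timing invariant to the overall
#'   normalization scale; set `latency_mode = "absolute"` to use a fixed
#'   `theta_resp` crossing instead;
#' * `duration_s`: latency crossing to response end, where the end is the
#'   last time the trace sits above `end_frac * peak_z`, walking forward from
#'   the peak and bridging sub-threshold dips shorter than `end_gap_s` (the
#'   neuronal valley transiently undercuts any threshold);
#' * `valley_time_s` (neurons): argmin within
#'   `(peak_time, peak_time + valley_window_s]`.
#'
#' @param ensemble An `"fp_ensemble"` from [build_ensemble()].
#' @param cell_type `"astro"` or `"neuron"`; sets the `peak_window_s` default
#'   (15 s astro, 5 s neuron) and whether valleys are measured.
#' @param theta_resp Responder threshold on the trial peak (z units).
#' @param latency_frac,end_frac Fractions of the trial peak defining response
#'   onset and end.
#' @param sustain_s Crossing must hold this long.
#' @param latency_window_s,peak_window_s,valley_window_s Search windows.
#' @param end_gap_s Maximum sub-threshold dip bridged when finding the end.
#' @param smooth_s Moving-mean width applied before measurement.
#' @param latency_mode `"fraction"` (default) or `"absolute"`.
#' @return A list of class `"fp_metrics"`: `trials` (tibble with one row per
#'   trial: `trial`, `responder`, `latency_s`, `peak_time_s`, `peak_z`,
#'   `duration_s`, `valley_time_s`), `summary` (mean +/- SEM over
#'   responders), `cell_type`, `params`.
#' @export
response_metrics <- function(ensemble, cell_type = c("astro", "neuron"),
                             theta_resp = 2, latency_frac = 0.15,
                             end_frac = 0.1, sustain_s = 0.33,
                             latency_window_s = 10, peak_window_s = NULL,
                             valley_window_s = 15, end_gap_s = 2,
                             smooth_s = 0.2,
                             latency_mode = c("fraction", "absolute")) {
  cell_type <- match.arg(cell_type)
  latency_mode <- match.arg(latency_mode)
  peak_window_s <- peak_window_s %||% if (cell_type == "astro") 15 else 5
  rate <- ensemble$rate_hz
  assert_that(ensemble$post_s >= peak_window_s,
              "post-window shorter than the peak search window")
  mat <- ensemble$matrix
  t_rel <- ensemble$time_s
  post <- which(t_rel > 0)
  nsm <- max(1L, round(smooth_s * rate))
  sus <- max(1L, round(sustain_s * rate))

  rows <- lapply(seq_len(nrow(mat)), function(i) {
    x <- as.numeric(stats::filter(mat[i, ], rep(1 / nsm, nsm), sides = 2))
    x[is.na(x)] <- mat[i, ][is.na(x)]
    xp <- x[post]
    tp <- t_rel[post]
    in_peak <- tp <= peak_window_s
    pk_i <- which.max(xp[in_peak])
    peak_z <- xp[in_peak][pk_i]
    peak_time <- tp[in_peak][pk_i]
    responder <- is.finite(peak_z) && peak_z >= theta_resp
    latency <- duration <- valley <- NA_real_
    if (responder) {
      thr_on <- if (latency_mode == "fraction") latency_frac * peak_z else theta_resp
      in_lat <- which(tp <= latency_window_s)
      above <- xp[in_lat] >= thr_on
      runs <- true_runs(above)
      runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= sus, , drop = FALSE]
      if (nrow(runs) > 0) latency <- tp[in_lat][runs[1, "start"]]
      if (!is.na(latency)) {
        thr_off <- end_frac * peak_z
        end_t <- response_end(xp, tp, peak_time, thr_off, sus,
                              round(end_gap_s * rate))
        duration <- end_t - latency
      }
      if (cell_type == "neuron") {
        in_val <- tp > peak_time & tp <= peak_time + valley_window_s
        if (any(in_val)) {
          vi <- which.min(xp[in_val])
          valley <- tp[in_val][vi]
        }
      }
    }
    tibble::tibble(trial = i, responder = responder, latency_s = latency,
                   peak_time_s = peak_time, peak_z = peak_z,
                   duration_s = duration, valley_time_s = valley)
  })
  trials <- dplyr::bind_rows(rows)
  assert_that(any(trials$responder), "all trials are non-responders")
  structure(list(trials = trials, summary = metrics_summary(trials),
                 cell_type = cell_type,
                 params = list(theta_resp = theta_resp,
                               latency_frac = latency_frac,
                               end_frac = end_frac, sustain_s = sustain_s,
                               latency_window_s = latency_window_s,
                               peak_window_s = peak_window_s,
                               valley_window_s = valley_window_s,
                               end_gap_s = end_gap_s, smooth_s = smooth_s,
                               latency_mode = latency_mode)),
            class = "fp_metrics")
}

# Mean +/- SEM per metric over responding trials.
metrics_summary <- function(trials) {
  resp <- trials[trials$responder, ]
  summarize1 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(mean = NA_real_, sem = NA_real_, n = 0))
    c(mean = mean(v), sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
      n = length(v))
  }
  purrr::map_dfr(c("latency_s", "peak_time_s", "peak_z", "duration_s",
                   "valley_time_s"),
                 function(m) {
                   s <- summarize1(resp[[m]])
                   tibble::tibble(metric = m, mean = s[["mean"]],
                                  sem = s[["sem"]], n = as.integer(s[["n"]]))
                 })
}

# Walk forward from the run containing the peak; the response is extended
# run-to-run while the next sustained (>= sus samples) supra-threshold run
# starts within gap_n samples of the current end. Unsustained blips neither
# extend the response nor reset the gap.
response_end <- function(xp, tp, peak_time, thr_off, sus, gap_n) {
  runs <- true_runs(xp >= thr_off)
  if (nrow(runs) == 0) return(peak_time)
  pk_i <- which(tp >= peak_time)[1]
  in_run <- runs[, "start"] <= pk_i & runs[, "end"] >= pk_i
  cur <- if (any(in_run)) which(in_run)[1] else {
    before <- which(runs[, "start"] <= pk_i)
    if (length(before)) max(before) else 1L
  }
  sustained <- runs[, "end"] - runs[, "start"] + 1L >= sus
  nxt <- cur + 1L
  while (nxt <= nrow(runs)) {
    if (runs[nxt, "start"] - runs[cur, "end"] - 1L > gap_n) break
    if (sustained[nxt]) cur <- nxt
    nxt <- nxt + 1L
  }
  tp[runs[cur, "end"]]
}

#' Paired astrocyte-neuron timing differences
#'
#' Per-trial differences between astrocytic and neuronal response metrics
#' from the same trials: `latency_diff_s` and `peak_diff_s` are astro minus
#' neuron (positive when the astrocyte is later, the typical case);
#' `astro_peak_to_neuron_valley_s` is the neuronal valley time minus the
#' astrocytic peak time (positive when the astrocytic peak precedes the
#' valley). Pairs where either trial is a non-responder are dropped.
#'
#' @param astro,neuron `"fp_metrics"` objects for the two cell types,
#'   computed from the same trial set.
#' @return A list of class `"fp_paired"`: `pairs` (per-trial tibble),
#'   `summary` (mean +/- SEM per difference).
#' @export
paired_differences <- function(astro, neuron) {
  a <- astro$trials; nn <- neuron$trials
  assert_that(nrow(a) == nrow(nn),
              "astro and neuron metrics have different trial counts (unpaired)")
  keep <- a$responder & nn$responder
  assert_that(any(keep), "no responding pairs")
  pairs <- tibble::tibble(
    trial = a$trial[keep],
    latency_diff_s = a$latency_s[keep] - nn$latency_s[keep],
    peak_diff_s = a$peak_time_s[keep] - nn$peak_time_s[keep],
    astro_peak_to_neuron_valley_s = nn$valley_time_s[keep] - a$peak_time_s[keep])
  summ <- purrr::map_dfr(
    c("latency_diff_s", "peak_diff_s", "astro_peak_to_neuron_valley_s"),
    function(m) {
      v <- pairs[[m]][!is.na(pairs[[m]])]
      tibble::tibble(metric = m,
                     mean = if (length(v)) mean(v) else NA_real_,
                     sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
                     n = length(v))
    })
  structure(list(pairs = pairs, summary = summ), class = "fp_paired")
}
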