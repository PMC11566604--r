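#' Generate synthetic open-field behavior
#'
#' Draws alternating stationary/movement intervals from a two-state renewal
#' process, simulates an arena trajectory (still while stationary, smooth
#' random walk at ~8 cm/s during bouts), and derives a ground-truth movement
#' index: per-frame centroid displacement divided by the body semi-major
#' length, lightly smoothed. Movement onsets are bout starts preceded by at
#' least `min_quiescence_s` of stationary time.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"fp_behavior"`:
#'   \describe{
#'     \item{movement}{tibble `time_s`, `index`, `x_cm`, `y_cm`}
#'     \item{segments}{tibble `start_s`, `end_s`, `label`}
#'     \item{onsets}{movement-onset times in seconds}
#'     \item{rate_hz, arena}{metadata carried from the config}
#'   }
#' @export
make_behavior <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)
  rate <- config$rate_hz
  n <- round(config$duration_s * rate)
  mb <- config$movement_bouts
  assert_that(mb$duration_mean_s > 0 && (mb$duration_sd_s %||% 0) >= 0,
              "bout durations must be positive")

  bouts <- draw_bouts(config$duration_s, mb)
  state <- rep("stationary", n)
  if (nrow(bouts) > 0) {
    for (i in seq_len(nrow(bouts))) {
      i0 <- time_to_sample(bouts$start_s[i], rate)
      i1 <- min(n, time_to_sample(bouts$end_s[i], rate) - 1L)
      state[i0:i1] <- "movement"
    }
  }

  traj <- draw_trajectory(state, rate, config$arena)
  disp_cm <- c(0, sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2))
  body_semimajor_cm <- 2.0   # matches the rendered blob in render_behavior_video()
  index <- disp_cm / body_semimajor_cm
  index <- as.numeric(stats::filter(index, rep(1 / 5, 5), sides = 2))
  index[is.na(index)] <- 0
  index[index < 0] <- 0

  segs <- state_run_segments(state, rate)
  onsets <- segment_onsets(segs, mb$min_quiescence_s)

  structure(list(
    movement = tibble::tibble(time_s = sample_to_time(seq_len(n), rate),
                              index = index, x_cm = traj$x_cm, y_cm = traj$y_cm),
    segments = segs,
    onsets = onsets,
    rate_hz = rate,
    arena = config$arena
  ), class = "fp_behavior")
}

# Renewal process: stationary gap (min_quiescence + exponential tail) then a
# bout of truncated-normal duration. The exponential tail mean defaults to
# whatever makes the long-run bout rate match rate_per_min, and can be pinned
# with movement_bouts$quiescence_extra_mean_s.
draw_bouts <- function(duration_s, mb) {
  if (mb$rate_per_min <= 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  cycle <- 60 / mb$rate_per_min
  extra_mean <- mb$quiescence_extra_mean_s %||%
    max(cycle - mb$min_quiescence_s - mb$duration_mean_s, 1)
  starts <- ends <- numeric()
  t <- 0
  repeat {
    gap <- mb$min_quiescence_s + rexp(1, 1 / extra_mean)
    dur <- rnorm(1, mb$duration_mean_s, mb$duration_sd_s %||% 0)
    dur <- max(dur, mb$duration_mean_s / 4, 0.5)
    t <- t + gap
    if (t + dur >= duration_s) break
    starts <- c(starts, t)
    ends <- c(ends, t + dur)
    t <- t + dur
  }
  tibble::tibble(start_s = starts, end_s = ends)
}

draw_trajectory <- function(state, rate, arena) {
  n <- length(state)
  margin <- 5                       # cm, keeps the rendered blob inside frame
  lo <- margin
  hi <- arena$size_cm - margin
  x <- y <- numeric(n)
  x[1] <- y[1] <- arena$size_cm / 2
  heading <- runif(1, 0, 2 * pi)
  turn <- rnorm(n, 0, 0.25)
  speed_target <- ifelse(state == "movement", 8, 0)  # cm/s
  # short ramp so the movement index rises smoothly at bout edges
  speed <- as.numeric(stats::filter(speed_target, rep(1 / 7, 7), sides = 2))
  speed[is.na(speed)] <- speed_target[is.na(speed)]
  for (i in 2:n) {
    heading <- heading + turn[i]
    step <- speed[i] / rate
    xn <- x[i - 1] + step * cos(heading)
    yn <- y[i - 1] + step * sin(heading)
    if (xn < lo || xn > hi) { heading <- pi - heading; xn <- pmin(pmax(xn, lo), hi) }
    if (yn < lo || yn > hi) { heading <- -heading;     yn <- pmin(pmax(yn, lo), hi) }
    x[i] <- xn; y[i] <- yn
  }
  list(x_cm = x, y_cm = y)
}

state_run_segments <- function(state, rate) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start_s = sample_to_time(starts, rate),
                 end_s = ends / rate,
                 label = r$values)
}

# Movement-segment starts preceded by >= min_quiescence_s of stationary time,
# read off the sampled segments so onsets sit on the sample grid.
segment_onsets <- function(segs, min_quiescence_s) {
  mv <- which(segs$label == "movement")
  mv <- mv[mv > 1]
  lead <- segs$end_s[mv - 1] - segs$start_s[mv - 1]
  segs$start_s[mv][lead >= min_quiescence_s]
}

#' Generate a footshock stimulus train
#'
#' Pulses of `pulse_s` seconds delivered at a fixed `interval_s`, starting at
#' `start_s`. The default configuration delivers 0.6 mA, 1 s shocks every
#' 5 min for four trials.
#'
#' @param config A [sim_config()] whose `footshock` element is non-NULL.
#' @return A tibble of class `"fp_stimuli"`: `onset_s`, `pulse_s`,
#'   `amplitude_mA`, `trial`.
#' @export
make_stimulus_train <- function(config) {
  fs <- config$footshock
  assert_that(!is.null(fs), "config$footshock is NULL; no stimulus train to build")
  assert_that(fs$n_trials >= 1, "footshock n_trials must be >= 1")
  assert_that(fs$interval_s > fs$pulse_s, "interval_s must exceed pulse_s")
  start <- fs$start_s %||% fs$interval_s
  onsets <- start + fs$interval_s * (seq_len(fs$n_trials) - 1)
  assert_that(all(onsets + fs$pulse_s <= config$duration_s),
              "stimulus train extends past the recording")
  structure(tibble::tibble(onset_s = onsets,
                           pulse_s = fs$pulse_s,
                           amplitude_mA = fs$amplitude_mA,
                           trial = seq_len(fs$n_trials)),
            class = c("fp_stimuli", "tbl_df", "tbl", "data.frame"))
}
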