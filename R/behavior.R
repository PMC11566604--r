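#' Binarize behavior video frames to delineate the mouse
#'
#' Converts grayscale frames to boolean mouse masks. With the default
#' dark-on-light polarity (dark mouse, white chamber floor) pixels below the
#' threshold are foreground. The threshold is either a fixed gray level or an
#' Otsu histogram split computed per frame. Frames that binarize to
#' all-foreground or all-background are flagged invalid rather than failing.
#'
#' @param video An `"fp_video"` object or a T x H x W numeric array.
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold Gray-level threshold for `method = "fixed"`.
#' @param dark_object If `FALSE`, bright-on-dark polarity.
#' @return A list of class `"fp_masks"`: `masks` (T x H x W logical array),
#'   `valid` (logical per frame), `rate_hz`, `px_per_cm` (when available).
#' @export
binarize_frames <- function(video, method = c("fixed", "otsu"),
                            threshold = 128, dark_object = TRUE) {
  method <- match.arg(method)
  frames <- if (is.list(video)) video$frames else video
  assert_that(length(dim(frames)) == 3 && dim(frames)[1] >= 1, "frames are empty")
  nT <- dim(frames)[1]
  masks <- array(FALSE, dim = dim(frames))
  valid <- logical(nT)
  for (t in seq_len(nT)) {
    fr <- frames[t, , ]
    thr <- if (method == "fixed") threshold else otsu_threshold(fr)
    m <- if (dark_object) fr < thr else fr > thr
    n_fg <- sum(m)
    valid[t] <- n_fg > 0 && n_fg < length(m)
    masks[t, , ] <- m
  }
  structure(list(masks = masks, valid = valid,
                 rate_hz = if (is.list(video)) video$rate_hz else NULL,
                 px_per_cm = if (is.list(video)) video$px_per_cm else NULL),
            class = "fp_masks")
}

# Otsu's histogram split: exhaustive search over 256 bins for the threshold
# maximizing between-class variance.
otsu_threshold <- function(fr) {
  v <- as.vector(fr)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])   # degenerate frame; caller flags it
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # the between-class variance plateaus across an empty histogram gap; the
  # plateau midpoint splits well-separated modes down the middle
  k <- round(mean(which(sigma_b == max(sigma_b))))
  breaks[k + 1]
}

#' Locate the mouse in binarized frames
#'
#' Keeps the largest connected component per valid frame; its pixel mean is
#' the centroid and its pixel count the body area. Invalid frames (and frames
#' whose largest component vanished) are linearly interpolated from their
#' neighbors; a gap of invalid frames longer than 1 s is an error.
#'
#' @param masks An `"fp_masks"` object from [binarize_frames()].
#' @param rate_hz Sampling rate; defaults to the one carried by `masks`.
#' @return A tibble: `frame`, `x_px`, `y_px`, `area_px`, `valid`.
#' @export
delineate_mouse <- function(masks, rate_hz = NULL) {
  rate_hz <- rate_hz %||% masks$rate_hz %||% 30
  arr <- masks$masks
  valid <- masks$valid
  assert_that(any(valid), "no valid frame to delineate")
  nT <- dim(arr)[1]
  x <- y <- area <- rep(NA_real_, nT)
  for (t in seq_len(nT)) {
    if (!valid[t]) next
    m <- arr[t, , ]
    lab <- EBImage::bwlabel(m)
    counts <- tabulate(lab[lab > 0])
    if (length(counts) == 0) { valid[t] <- FALSE; next }
    big <- which.max(counts)
    idx <- which(lab == big, arr.ind = TRUE)
    # column index is x (horizontal), row index is y; pixel centers at i - 0.5
    x[t] <- mean(idx[, 2]) - 0.5
    y[t] <- mean(idx[, 1]) - 0.5
    area[t] <- counts[big]
  }
  gaps <- true_runs(!valid)
  if (nrow(gaps) > 0 && max(gaps[, "end"] - gaps[, "start"] + 1) > rate_hz) {
    stop("gap of invalid frames longer than 1 s", call. = FALSE)
  }
  interp <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(!is.na(v))
    approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  tibble::tibble(frame = seq_len(nT), x_px = interp(x), y_px = interp(y),
                 area_px = interp(area), valid = valid)
}

#' Body-size-normalized movement index from binarized frames
#'
#' `index[t]` is the symmetric-difference pixel count between the masks at
#' frames t and t-1, divided by the mean body area of the two frames -
#' movement relative to body size. `index[1] = 0`. Degenerate transitions
#' (appearance from or disappearance to an empty frame) are capped at `cap`
#' and flagged.
#'
#' @param masks An `"fp_masks"` object.
#' @param body_area Per-frame body areas (e.g. from [delineate_mouse()]);
#'   defaults to the mask pixel counts.
#' @param cap Ceiling applied to degenerate transitions.
#' @return A tibble: `frame`, `index`, `capped`.
#' @export
movement_index <- function(masks, body_area = NULL, cap = 2) {
  arr <- masks$masks
  nT <- dim(arr)[1]
  assert_that(nT >= 2, "movement index requires at least two frames")
  flat <- matrix(arr, nrow = nT)
  if (is.null(body_area)) body_area <- rowSums(flat)
  index <- numeric(nT)
  capped <- logical(nT)
  for (t in 2:nT) {
    sym <- sum(xor(flat[t, ], flat[t - 1, ]))
    a0 <- body_area[t - 1]; a1 <- body_area[t]
    denom <- mean(c(a0, a1))
    degenerate <- !is.finite(denom) || denom <= 0 ||
      min(a0, a1, na.rm = TRUE) <= 0
    if (degenerate) {
      index[t] <- cap; capped[t] <- TRUE
    } else {
      index[t] <- sym / denom
      if (index[t] > cap) { index[t] <- cap; capped[t] <- TRUE }
    }
  }
  tibble::tibble(frame = seq_len(nT), index = index, capped = capped)
}

#' Segment a session into stationary and movement states
#'
#' A movement segment is a run of `index > theta_move` sustained for at least
#' `min_move_s`; sub-threshold gaps shorter than `bridge_s` are bridged
#' first. Everything else is stationary. Movement onsets are the starts of
#' movement segments preceded by at least `min_quiescence_s` of stationary
#' time (segments without that quiescent lead-in are still labeled movement
#' but are excluded from the onset list).
#'
#' @param index Movement-index vector (or tibble from [movement_index()]).
#' @param rate_hz Frames per second.
#' @param theta_move Index threshold.
#' @param min_move_s Minimum sustained supra-threshold time.
#' @param min_quiescence_s Minimum stationary lead-in for an onset.
#' @param bridge_s Maximum sub-threshold gap to bridge.
#' @return A list of class `"fp_states"`: `segments` (tibble `start_s`,
#'   `end_s`, `label`), `onsets` (seconds), plus the parameters used.
#' @export
segment_states <- function(index, rate_hz, theta_move = 0.05,
                           min_move_s = 1, min_quiescence_s = 3,
                           bridge_s = 0.5) {
  if (is.data.frame(index)) index <- index$index
  n <- length(index)
  assert_that(n >= rate_hz * (min_move_s + min_quiescence_s),
              "index too short to segment")
  above <- index > theta_move
  # bridge short gaps
  gaps <- true_runs(!above)
  for (i in seq_len(nrow(gaps))) {
    s <- gaps[i, "start"]; e <- gaps[i, "end"]
    if (s > 1 && e < n && (e - s + 1) < bridge_s * rate_hz) above[s:e] <- TRUE
  }
  # drop unsustained movement runs
  runs <- true_runs(above)
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, "start"]; e <- runs[i, "end"]
    if ((e - s + 1) < min_move_s * rate_hz) above[s:e] <- FALSE
  }
  segs <- state_run_segments(ifelse(above, "movement", "stationary"), rate_hz)
  mv <- segs[segs$label == "movement", ]
  onsets <- numeric()
  if (nrow(mv) > 0) {
    prev_end <- vapply(mv$start_s, function(s) {
      before <- segs[segs$end_s <= s + 1e-9 & segs$label == "stationary", ]
      if (nrow(before) == 0) return(NA_real_)
      b <- before[nrow(before), ]
      if (abs(b$end_s - s) < 1e-9) b$end_s - b$start_s else NA_real_
    }, numeric(1))
    lead <- ifelse(is.na(prev_end), 0, prev_end)
    # a bout starting at t = 0 has no observed quiescent lead-in
    onsets <- mv$start_s[lead >= min_quiescence_s]
  }
  structure(list(segments = segs, onsets = onsets,
                 params = list(theta_move = theta_move, min_move_s = min_move_s,
                               min_quiescence_s = min_quiescence_s,
                               bridge_s = bridge_s, rate_hz = rate_hz)),
            class = "fp_states")
}

#' Convert the tracked centroid to arena coordinates and speed
#'
#' @param centroids Tibble from [delineate_mouse()] (columns `x_px`, `y_px`).
#' @param px_per_cm Pixel-to-centimeter scale (> 0).
#' @param rate_hz Frames per second.
#' @return Tibble: `time_s`, `x_cm`, `y_cm`, `speed_cm_s`.
#' @export
trajectory <- function(centroids, px_per_cm, rate_hz) {
  assert_that(!is.null(px_per_cm) && is.finite(px_per_cm) && px_per_cm > 0,
              "missing or invalid arena scale (px_per_cm)")
  x <- centroids$x_px / px_per_cm
  y <- centroids$y_px / px_per_cm
  disp <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  tibble::tibble(time_s = (centroids$frame - 1) / rate_hz,
                 x_cm = x, y_cm = y, speed_cm_s = disp * rate_hz)
}
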