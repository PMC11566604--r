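#' Render a synthetic fiber-bundle image stack from raw traces
#'
#' Draws one uniform disc per (region, channel) on a constant background, with
#' the disc intensity at frame t equal to the corresponding raw-fluorescence
#' sample. Together with [extract_roi_traces()] this closes a round-trip:
#' mean intensity inside each ROI recovers the trace exactly (quantization
#' below 0.5 gray levels when written to disk).
#'
#' @param sim An `"fp_sim"` object (or any list with a `traces` long tibble).
#' @param layout Optional tibble `name`, `cx`, `cy`, `r` (pixel centers/radii).
#'   Defaults to a grid with one disc per trace channel. Discs must not
#'   overlap.
#' @param width,height Frame size in pixels.
#' @param background Background gray level.
#' @param every Temporal downsampling stride (render every `every`-th sample).
#' @return A list of class `"fp_stack"`: `frames` (T x H x W array),
#'   `roi_masks` (named list of logical H x W matrices), `timestamps`.
#' @export
render_fiber_bundle_frames <- function(sim, layout = NULL,
                                       width = 64, height = 64,
                                       background = 10, every = 1L) {
  traces <- tidyr::pivot_wider(sim$traces,
                               id_cols = "time_s",
                               names_from = c("region", "channel"),
                               values_from = "value", names_sep = ".")
  keep <- seq(1, nrow(traces), by = every)
  traces <- traces[keep, ]
  chans <- setdiff(names(traces), "time_s")
  if (is.null(layout)) layout <- default_bundle_layout(chans, width, height)
  assert_that(nrow(layout) >= 1, "layout is empty")
  assert_that(all(layout$name %in% chans) && all(chans %in% layout$name),
              "layout names must match trace channels")

  masks <- lapply(seq_len(nrow(layout)), function(i) {
    disc_mask(height, width, layout$cx[i], layout$cy[i], layout$r[i])
  })
  names(masks) <- layout$name
  for (i in seq_along(masks)) {
    assert_that(any(masks[[i]]), sprintf("ROI '%s' is empty", names(masks)[i]))
  }
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  assert_that(max(overlap) <= 1L, "layout places overlapping discs")

  nT <- nrow(traces)
  frames <- array(background, dim = c(nT, height, width))
  for (ch in layout$name) {
    m <- which(masks[[ch]])
    v <- traces[[ch]]
    for (t in seq_len(nT)) {
      fr <- frames[t, , ]
      fr[m] <- v[t]
      frames[t, , ] <- fr
    }
  }
  structure(list(frames = frames, roi_masks = masks,
                 timestamps = traces$time_s),
            class = "fp_stack")
}

default_bundle_layout <- function(chans, width, height) {
  k <- length(chans)
  ncol_ <- ceiling(sqrt(k))
  nrow_ <- ceiling(k / ncol_)
  r <- floor(min(width / ncol_, height / nrow_) / 2) - 2
  assert_that(r >= 2, "frame too small for the requested channel count")
  idx <- seq_len(k) - 1L
  tibble::tibble(
    name = chans,
    cx = (idx %% ncol_) * (width / ncol_) + width / ncol_ / 2,
    cy = (idx %/% ncol_) * (height / nrow_) + height / nrow_ / 2,
    r = r)
}

disc_mask <- function(height, width, cx, cy, r) {
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Render synthetic behavior video frames
#'
#' Draws a dark elliptical blob (the mouse, semi-axes 2 x 1.25 cm) on a bright
#' background at the ground-truth centroid of each frame, mimicking a
#' top-down camera over a white 40 x 40 cm open-field chamber. The default
#' frame size is a scaled-down 160 x 90; pass `width_px`/`height_px` in the
#' config `arena` for other resolutions (e.g. the full 1280 x 720).
#'
#' @param behavior An `"fp_behavior"` object from [make_behavior()].
#' @param arena Optional override of `behavior$arena`.
#' @param blob_gray,background_gray Gray levels of mouse and floor.
#' @return A list of class `"fp_video"`: `frames` (T x H x W numeric array),
#'   `rate_hz`, `px_per_cm`, `arena`.
#' @export
render_behavior_video <- function(behavior, arena = NULL,
                                  blob_gray = 20, background_gray = 240) {
  arena <- arena %||% behavior$arena
  # isotropic scale from the short frame side; the square arena occupies the
  # left portion of a wide frame
  px_per_cm <- arena$height_px / arena$size_cm
  a_px <- 2.0 * px_per_cm     # semi-major (cm -> px); keep in sync with make_behavior
  b_px_y <- 1.25 * px_per_cm
  x_px <- behavior$movement$x_cm * px_per_cm
  y_px <- behavior$movement$y_cm * px_per_cm
  assert_that(all(x_px - a_px >= 0) && all(x_px + a_px <= arena$width_px) &&
                all(y_px - b_px_y >= 0) && all(y_px + b_px_y <= arena$height_px),
              "trajectory leaves the arena bounds")
  nT <- length(x_px)
  H <- arena$height_px; W <- arena$width_px
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
  ys <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
  frames <- array(background_gray, dim = c(nT, H, W))
  for (t in seq_len(nT)) {
    inside <- ((xs - x_px[t]) / a_px)^2 + ((ys - y_px[t]) / b_px_y)^2 <= 1
    fr <- frames[t, , ]
    fr[inside] <- blob_gray
    frames[t, , ] <- fr
  }
  structure(list(frames = frames, rate_hz = behavior$rate_hz,
                 px_per_cm = px_per_cm, arena = arena),
            class = "fp_video")
}
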