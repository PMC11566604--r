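#' Extract per-ROI mean-intensity traces from an image stack
#'
#' For every ROI mask, the trace value at frame t is the arithmetic mean of
#' the pixel intensities inside the mask - the raw calcium signal Fraw of
#' fiber photometry, where each disc of the fiber-bundle image is one
#' (region, channel) pair.
#'
#' @param stack An `"fp_stack"` (see [render_fiber_bundle_frames()]) or a list
#'   with `frames` (T x H x W array), `roi_masks` (named list of logical
#'   matrices) and optional `timestamps`.
#' @return A long tibble `time_s`, `roi`, `value`.
#' @export
extract_roi_traces <- function(stack) {
  frames <- stack$frames
  masks <- stack$roi_masks
  assert_that(length(masks) >= 1, "no ROI masks supplied")
  nT <- dim(frames)[1]
  ts <- stack$timestamps %||% (seq_len(nT) - 1)
  flat <- matrix(frames, nrow = nT)   # T x (H*W), column-major over (H, W)
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    assert_that(any(m), sprintf("ROI '%s' has an empty mask", nm))
    idx <- which(as.vector(m))
    tibble::tibble(time_s = ts, roi = nm,
                   value = rowMeans(flat[, idx, drop = FALSE]))
  })
  dplyr::bind_rows(out)
}

#' Moving-window baseline of a raw fluorescence trace
#'
#' Centered (default) or trailing moving mean with edge windows truncated to
#' the available samples, so the output has the same length as the input.
#'
#' @param x Numeric trace (Fraw).
#' @param rate_hz Sampling rate.
#' @param window_s Window length in seconds; must cover at least 2 samples.
#' @param align `"center"` or `"trailing"`.
#' @return Baseline vector, same length as `x`.
#' @export
moving_baseline <- function(x, rate_hz, window_s = 90, align = c("center", "trailing")) {
  align <- match.arg(align)
  w <- round(window_s * rate_hz)
  assert_that(w >= 2, "baseline window must cover at least 2 samples")
  n <- length(x)
  i <- seq_len(n)
  if (align == "center") {
    h_left <- (w - 1L) %/% 2L
    h_right <- w - 1L - h_left
    lo <- pmax(1L, i - h_left)
    hi <- pmin(n, i + h_right)
  } else {
    lo <- pmax(1L, i - w + 1L)
    hi <- i
  }
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fractional fluorescence change
#'
#' `dff = (Fraw - Fbaseline) / Fbaseline`. The baseline must be strictly
#' positive everywhere; a non-positive baseline signals invalid fluorescence
#' input rather than something to silently patch.
#'
#' @param x Raw trace.
#' @param baseline Baseline trace of the same length.
#' @return dF/F vector.
#' @export
compute_dff <- function(x, baseline) {
  assert_that(length(x) == length(baseline), "trace and baseline lengths differ")
  assert_that(all(baseline > 0), "baseline must be strictly positive everywhere")
  (x - baseline) / baseline
}

#' z-score a dF/F trace
#'
#' `z = (dff - mean) / sd` with the population (1/n) standard deviation over
#' `span` (default: the full recording), so the normalized trace has exactly
#' zero mean and unit variance over its normalization span.
#'
#' @param x dF/F vector.
#' @param span Optional integer index vector giving the normalization span.
#' @return z-scored vector (same length as `x`).
#' @export
compute_zscore <- function(x, span = NULL) {
  span <- span %||% seq_along(x)
  m <- mean(x[span])
  s <- pop_sd(x[span])
  assert_that(is.finite(s) && s > 0,
              "zero standard deviation over the normalization span (constant input)")
  (x - m) / s
}

#' Normalize raw traces to baseline, dF/F and z-score
#'
#' Grouped pipeline over a long trace table: per (region, channel), computes
#' the moving-window baseline, dF/F and the session z-score. This is the
#' standard preprocessing applied before transient detection and
#' connectivity analysis.
#'
#' @param traces Long tibble with columns `time_s`, `region`, `channel`,
#'   `value` (e.g. `sim$traces` or [extract_roi_traces()] output after
#'   splitting the `roi` key).
#' @param rate_hz Sampling rate.
#' @param window_s Baseline window in seconds. The default (90 s) is set well
#'   above the longest typical astrocytic transient so slow events survive
#'   baseline subtraction, while still tracking photobleaching drift.
#' @param align Baseline alignment, see [moving_baseline()].
#' @return The input tibble with `baseline`, `dff`, `z` columns added.
#' @export
process_traces <- function(traces, rate_hz, window_s = 90,
                           align = c("center", "trailing")) {
  align <- match.arg(align)
  dplyr::mutate(
    dplyr::group_by(traces, .data$region, .data$channel),
    baseline = moving_baseline(.data$value, rate_hz, window_s, align),
    dff = compute_dff(.data$value, .data$baseline),
    z = compute_zscore(.data$dff),
    .keep = "all") |>
    dplyr::ungroup()
}

#' Map stream timestamps onto the photometry clock via shared event markers
#'
#' Piecewise-linear interpolation between markers observed on both clocks;
#' outside the marker range the mapping extrapolates linearly from the
#' nearest marker segment. With a single shared marker the mapping is a pure
#' offset. Residual offset at the markers themselves is zero by construction.
#'
#' @param times Timestamps on the stream clock (e.g. video).
#' @param stream_markers Marker times on the stream clock.
#' @param ref_markers The same markers on the reference (photometry) clock.
#' @return `times` re-expressed on the reference clock.
#' @export
synchronize <- function(times, stream_markers, ref_markers) {
  assert_that(length(stream_markers) == length(ref_markers),
              "marker vectors must pair up")
  assert_that(length(stream_markers) >= 1, "no shared markers between streams")
  if (length(stream_markers) == 1) {
    return(times + (ref_markers - stream_markers))
  }
  o <- order(stream_markers)
  sm <- stream_markers[o]; rm_ <- ref_markers[o]
  inside <- approx(sm, rm_, xout = times, rule = 2)$y
  # linear extrapolation beyond the outermost markers
  k1 <- (rm_[2] - rm_[1]) / (sm[2] - sm[1])
  kN <- (rm_[length(rm_)] - rm_[length(rm_) - 1]) /
    (sm[length(sm)] - sm[length(sm) - 1])
  lo <- times < sm[1]
  hi <- times > sm[length(sm)]
  inside[lo] <- rm_[1] + k1 * (times[lo] - sm[1])
  inside[hi] <- rm_[length(rm_)] + kN * (times[hi] - sm[length(sm)])
  inside
}
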