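test_that("frame binarization separates dark blob from bright background", {
  fr <- matrix(240, 30, 30)
  fr[10:19, 10:19] <- 20
  frames <- array(fr, dim = c(1, 30, 30))
  bm <- binarize_frames(frames, method = "fixed", threshold = 128)
  expect_true(bm$valid[1])
  expect_equal(sum(bm$masks[1, , ]), 100)
  expect_true(all(bm$masks[1, 10:19, 10:19]))

  # blank frame flagged invalid, not fatal
  blank <- array(240, dim = c(1, 30, 30))
  bb <- binarize_frames(blank, method = "fixed", threshold = 128)
  expect_false(bb$valid[1])

  # Otsu threshold lies between the two modes and induces the same partition
  # as an exhaustive between-class-variance search over all candidate splits
  set.seed(1)
  vals <- c(rnorm(300, 40, 6), rnorm(600, 210, 8))
  fr2 <- matrix(sample(vals, 900), 30, 30)
  bo <- binarize_frames(array(fr2, dim = c(1, 30, 30)), method = "otsu")
  thr_pkg <- glianet:::otsu_threshold(fr2)
  expect_gt(thr_pkg, max(vals[vals < 120]))
  expect_lt(thr_pkg, min(vals[vals > 120]))
  cands <- sort(unique(as.vector(fr2)))
  between_var <- vapply(cands, function(th) {
    lo <- as.vector(fr2)[as.vector(fr2) < th]; hi <- as.vector(fr2)[as.vector(fr2) >= th]
    if (!length(lo) || !length(hi)) return(0)
    length(lo) * length(hi) / 900^2 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  thr_oracle <- cands[which.max(between_var)]
  expect_identical(fr2 < thr_pkg, fr2 < thr_oracle)
  expect_equal(sum(bo$masks[1, , ]), sum(fr2 < thr_oracle))
})

test_that("mouse delineation keeps the largest component and interpolates gaps", {
  H <- 20; W <- 20
  mk <- function(fill) {
    m <- matrix(FALSE, H, W); m[fill] <- TRUE; m
  }
  sq <- matrix(FALSE, H, W); sq[6:15, 6:15] <- TRUE      # 10x10 blob
  speck <- sq; speck[2, 2] <- TRUE; speck[2, 3] <- TRUE; speck[3, 2] <- TRUE
  arr <- array(FALSE, dim = c(3, H, W))
  arr[1, , ] <- sq; arr[2, , ] <- speck; arr[3, , ] <- sq
  masks <- list(masks = arr, valid = rep(TRUE, 3), rate_hz = 30)
  dm <- delineate_mouse(masks)
  expect_equal(dm$area_px, rep(100, 3))                   # speckle ignored
  expect_equal(dm$x_px, rep(10, 3))                       # center of cols 6..15
  expect_equal(dm$y_px, rep(10, 3))

  # invalid middle frame interpolated
  arr2 <- arr
  arr2[2, , ] <- FALSE
  masks2 <- list(masks = arr2, valid = c(TRUE, FALSE, TRUE), rate_hz = 30)
  dm2 <- delineate_mouse(masks2)
  expect_equal(dm2$x_px[2], 10)
  expect_equal(dm2$area_px[2], 100)

  # long invalid gap errors
  arr3 <- array(FALSE, dim = c(40, H, W))
  arr3[1, , ] <- sq; arr3[40, , ] <- sq
  masks3 <- list(masks = arr3, valid = c(TRUE, rep(FALSE, 38), TRUE), rate_hz = 30)
  expect_error(delineate_mouse(masks3), "longer than 1 s")
})

test_that("movement index equals symmetric difference over body area", {
  H <- 20; W <- 20
  sq1 <- matrix(FALSE, H, W); sq1[6:15, 6:15] <- TRUE
  sq2 <- matrix(FALSE, H, W); sq2[6:15, 8:17] <- TRUE     # 2 px horizontal shift
  arr <- array(FALSE, dim = c(3, H, W))
  arr[1, , ] <- sq1; arr[2, , ] <- sq1; arr[3, , ] <- sq2
  masks <- list(masks = arr, valid = rep(TRUE, 3))
  mi <- movement_index(masks)
  expect_equal(mi$index[1], 0)
  expect_equal(mi$index[2], 0)          # identical consecutive masks
  expect_equal(mi$index[3], 40 / 100)   # 2*2*10 changed pixels / area 100

  # appearance from an empty frame capped and flagged
  arr2 <- array(FALSE, dim = c(2, H, W))
  arr2[2, , ] <- sq1
  mi2 <- movement_index(list(masks = arr2, valid = c(FALSE, TRUE)))
  expect_equal(mi2$index[2], 2)
  expect_true(mi2$capped[2])
})

test_that("state segmentation finds square-wave onsets and enforces quiescence", {
  rate <- 30
  # all-zero index: one stationary segment, no onsets
  st0 <- segment_states(rep(0, 600), rate)
  expect_equal(nrow(st0$segments), 1)
  expect_equal(st0$segments$label, "stationary")
  expect_length(st0$onsets, 0)

  # square wave 10 s on / 20 s off: onsets at each rising edge after the first
  idx <- rep(c(rep(0, 20 * rate), rep(1, 10 * rate)), 4)
  st <- segment_states(idx, rate)
  rising <- 20 + (0:3) * 30
  expect_equal(st$onsets, rising, tolerance = 1e-9)
  # segments partition the session
  segs <- st$segments
  expect_equal(segs$start_s[1], 0)
  expect_equal(segs$end_s[nrow(segs)], length(idx) / rate)
  expect_true(all(abs(segs$start_s[-1] - segs$end_s[-nrow(segs)]) < 1e-9))

  # a bout with only 1 s of preceding quiescence is movement but not an onset
  idx2 <- c(rep(0, 5 * rate), rep(1, 5 * rate), rep(0, 1 * rate),
            rep(1, 5 * rate), rep(0, 10 * rate))
  st2 <- segment_states(idx2, rate, bridge_s = 0.5)
  mv <- st2$segments[st2$segments$label == "movement", ]
  expect_equal(nrow(mv), 2)
  expect_equal(st2$onsets, 5)

  # gaps under bridge_s are bridged into one bout
  idx3 <- c(rep(0, 5 * rate), rep(1, 3 * rate), rep(0, 0.3 * rate),
            rep(1, 3 * rate), rep(0, 10 * rate))
  st3 <- segment_states(idx3, rate)
  expect_equal(sum(st3$segments$label == "movement"), 1)
})

test_that("trajectory converts pixels to cm and differentiates speed", {
  cent <- tibble::tibble(frame = 1:31, x_px = seq(0, 30), y_px = rep(5, 31))
  tr <- trajectory(cent, px_per_cm = 10, rate_hz = 30)
  expect_equal(tr$speed_cm_s[1], 0)
  expect_equal(tr$speed_cm_s[-1], rep(3, 30))  # 1 px/frame at 0.1 cm/px, 30 Hz
  expect_error(trajectory(cent, px_per_cm = NULL, rate_hz = 30), "scale")

  static <- tibble::tibble(frame = 1:10, x_px = rep(3, 10), y_px = rep(4, 10))
  expect_true(all(trajectory(static, 10, 30)$speed_cm_s == 0))
})

test_that("rendered video round-trips trajectory, states and onsets", {
  cfg <- sim_config(duration_s = 150, regions = "M1",
                    movement_bouts = list(rate_per_min = 2, duration_mean_s = 5,
                                          duration_sd_s = 1, min_quiescence_s = 3),
                    seed = 11)
  beh <- make_behavior(cfg)
  vid <- render_behavior_video(beh)
  bm <- binarize_frames(vid, method = "fixed", threshold = 128)
  dm <- delineate_mouse(bm)

  px <- vid$px_per_cm
  err <- sqrt((dm$x_px - beh$movement$x_cm * px)^2 +
                (dm$y_px - beh$movement$y_cm * px)^2)
  expect_lt(max(err), 1)                        # centroid within 1 px
  expect_true(all(dm$area_px > 0))
  # body area constant across frames (same ellipse up to rasterization)
  expect_lt(diff(range(dm$area_px)) / mean(dm$area_px), 0.2)

  mi <- movement_index(bm, dm$area_px)
  st <- segment_states(mi$index, 30)
  # static blob while stationary: index exactly 0 well inside those segments
  stat <- beh$segments[beh$segments$label == "stationary", ]
  mid <- (stat$start_s + stat$end_s) / 2
  mid_idx <- round(mid * 30) + 1
  expect_true(all(mi$index[mid_idx] < 0.01))

  # segment boundaries near ground truth; onset recall/precision
  near <- function(a, b, tol = 1) vapply(a, function(x) min(abs(b - x)) <= tol,
                                         logical(1))
  expect_gte(mean(near(beh$onsets, st$onsets)), 0.9)
  expect_gte(mean(near(st$onsets, beh$onsets)), 0.9)

  # path length against ground truth
  tr <- trajectory(dm, px, 30)
  true_len <- sum(sqrt(diff(beh$movement$x_cm)^2 + diff(beh$movement$y_cm)^2))
  expect_lt(abs(sum(tr$speed_cm_s / 30) - true_len) / true_len, 0.02)
})

test_that("movement index is invariant to brightness changes preserving binarization", {
  cfg <- sim_config(duration_s = 60, regions = "M1",
                    movement_bouts = list(rate_per_min = 3, duration_mean_s = 5,
                                          duration_sd_s = 1, min_quiescence_s = 2),
                    seed = 12)
  beh <- make_behavior(cfg)
  v1 <- render_behavior_video(beh, blob_gray = 20, background_gray = 240)
  v2 <- render_behavior_video(beh, blob_gray = 60, background_gray = 200)
  m1 <- movement_index(binarize_frames(v1, threshold = 128))
  m2 <- movement_index(binarize_frames(v2, threshold = 128))
  expect_equal(m1$index, m2$index)
})
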