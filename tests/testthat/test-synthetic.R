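test_that("transient kernel peaks at the configured time and scales with amplitude", {
  astro <- sim_config()$astro_kinetics
  k <- transient_kernel(astro, 30)
  t <- attr(k, "time_s")
  expect_equal(t[which.max(k)], 5.66, tolerance = 1 / 30 + 1e-9)
  expect_equal(max(k), astro$amplitude_z)
  expect_true(all(k >= 0))

  neuron <- sim_config()$neuron_kinetics
  kn <- transient_kernel(neuron, 30)
  expect_equal(attr(kn, "time_s")[which.max(kn)], 1.07, tolerance = 1 / 30 + 1e-9)

  z0 <- transient_kernel(modifyList(astro, list(amplitude_z = 0)), 30)
  expect_true(all(z0 == 0))

  # zero before the onset latency, sharp rise right after
  expect_true(all(k[t < astro$onset_latency_s] == 0))
  expect_gt(k[which(t >= astro$onset_latency_s + 0.2)[1]], 0.3 * astro$amplitude_z)

  expect_error(transient_kernel(list(onset_latency_s = 2, peak_time_s = 1,
                                     duration_s = 10, amplitude_z = 1), 30),
               "onset < peak")
})

test_that("behavior generator: bout counts, no-bout case, quiescence rule", {
  cfg <- sim_config(duration_s = 600, regions = "M1",
                    movement_bouts = list(rate_per_min = 2, duration_mean_s = 6,
                                          duration_sd_s = 2, min_quiescence_s = 3),
                    seed = 3)
  beh <- make_behavior(cfg)
  n_bouts <- sum(beh$segments$label == "movement")
  # renewal process with rate 2/min over 600 s: expect 20 +/- Poisson error
  expect_gt(n_bouts, 20 - 3 * sqrt(20))
  expect_lt(n_bouts, 20 + 3 * sqrt(20))

  # every onset preceded by >= min_quiescence_s of stationary time
  segs <- beh$segments
  for (o in beh$onsets) {
    prev <- segs[abs(segs$end_s - o) < 1e-9 & segs$label == "stationary", ]
    expect_equal(nrow(prev), 1)
    expect_gte(prev$end_s - prev$start_s, 3)
  }

  # rate 0: a single stationary segment spanning the recording
  cfg0 <- sim_config(duration_s = 120, regions = "M1",
                     movement_bouts = list(rate_per_min = 0, duration_mean_s = 6,
                                           duration_sd_s = 2, min_quiescence_s = 3))
  beh0 <- make_behavior(cfg0)
  expect_equal(nrow(beh0$segments), 1)
  expect_equal(beh0$segments$label, "stationary")
  expect_equal(beh0$segments$start_s, 0)
  expect_equal(beh0$segments$end_s, 120)
  expect_length(beh0$onsets, 0)

  # segments partition [0, duration)
  expect_equal(beh$segments$start_s[1], 0)
  expect_equal(beh$segments$end_s[nrow(segs)], 600)
  expect_true(all(abs(segs$start_s[-1] - segs$end_s[-nrow(segs)]) < 1e-9))
})

test_that("stimulus train matches the 5-min 4-trial footshock protocol", {
  cfg <- sim_footshock_config()
  st <- make_stimulus_train(cfg)
  expect_equal(st$onset_s, c(300, 600, 900, 1200))
  expect_equal(unique(st$pulse_s), 1)
  expect_equal(unique(st$amplitude_mA), 0.6)
  # 1 s pulse at 30 Hz spans 30 samples
  expect_equal(unique(st$pulse_s) * cfg$rate_hz, 30)

  st1 <- make_stimulus_train(sim_footshock_config(n_trials = 1))
  expect_equal(nrow(st1), 1)
  expect_true(all(diff(st$onset_s) > 0))

  bad <- sim_footshock_config()
  bad$footshock$n_trials <- 0
  expect_error(make_stimulus_train(bad), "n_trials")
})

test_that("simulated recordings are deterministic and ground truth is consistent", {
  cfg <- quick_config(seed = 5)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(quick_config(seed = 5))
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$ground_truth$events, s2$ground_truth$events)

  gt <- s1$ground_truth$events
  expect_true(all(gt$onset_s < gt$peak_s))
  expect_true(all(gt$peak_s < gt$end_s))

  # one astro and one neuron event per movement onset per region
  n_on <- length(s1$behavior$onsets)
  mv <- gt[gt$trigger == "movement", ]
  expect_equal(sum(mv$cell_type == "astro"), n_on * length(cfg$regions))
  expect_equal(sum(mv$cell_type == "neuron"), n_on * length(cfg$regions))
})

test_that("ground-truth amplitudes and durations encode the study phenomenology", {
  cfg <- sim_config(duration_s = 1800, regions = "M1", seed = 7)
  gt <- simulate_recording(cfg)$ground_truth$events
  astro <- gt[gt$cell_type == "astro", ]
  neuron <- gt[gt$cell_type == "neuron", ]

  # movement vs stationary (microdomain) amplitude ratio = 10 by construction
  expect_equal(cfg$microdomain$amplitude_fraction, 0.1)
  mv_amp <- mean(astro$amplitude[astro$trigger == "movement"])
  md_amp <- mean(astro$amplitude[astro$trigger == "microdomain"])
  expect_equal(mv_amp / md_amp, 10, tolerance = 0.25)

  # duration dichotomy at 20 s in ground truth
  expect_gte(mean(astro$end_s - astro$onset_s > 20), 0.8)
  expect_gte(mean(neuron$end_s - neuron$onset_s < 20), 0.8)
})

test_that("eventless, noiseless config reduces to the bleach curve", {
  cfg <- sim_config(duration_s = 120, regions = "M1",
                    movement_bouts = list(rate_per_min = 0, duration_mean_s = 6,
                                          duration_sd_s = 0, min_quiescence_s = 3),
                    microdomain = list(rate_per_min = 0, amplitude_fraction = 0.1,
                                       duration_mean_s = 25, duration_sd_s = 5),
                    coupling = list(movement = 0.85, stationary = 0.3,
                                    drive_sd = 0, noise_sd = 0))
  sim <- simulate_recording(cfg)
  v <- sim$traces$value[sim$traces$channel == "astro"]
  t <- sim$traces$time_s[sim$traces$channel == "astro"]
  bleach <- cfg$f0 * ((1 - 0.2) + 0.2 * exp(-t / 1200))
  expect_equal(v, bleach, tolerance = 1e-12)
  expect_equal(nrow(sim$ground_truth$events), 0)
})

test_that("control channels carry no events and shared drive is state-dependent", {
  cfg <- quick_config(seed = 9, control_channels = TRUE)
  sim <- simulate_recording(cfg)
  expect_true(all(sim$ground_truth$events$cell_type %in% c("astro", "neuron")))
  expect_setequal(unique(sim$traces$channel),
                  c("astro", "neuron", "gfp", "mcherry"))

  # noiseless drive correlation is strictly greater during movement:
  # mix the recorded global drive at the two state weights with an
  # independent private component and compare
  cp <- cfg$coupling
  g <- sim$ground_truth$drive
  set.seed(1)
  h1 <- rnorm(length(g)); h2 <- rnorm(length(g))
  mk <- function(c_, h) sqrt(c_) * g + sqrt(1 - c_) * h
  r_mv <- cor(mk(cp$movement, h1), mk(cp$movement, h2))
  r_st <- cor(mk(cp$stationary, h1), mk(cp$stationary, h2))
  expect_gt(r_mv, r_st)
})

test_that("fiber-bundle rendering round-trips raw traces through ROI extraction", {
  cfg <- sim_config(duration_s = 60, regions = "M1", seed = 2)
  sim <- simulate_recording(cfg)
  stack <- render_fiber_bundle_frames(sim, width = 48, height = 48, every = 10L)
  rec <- extract_roi_traces(stack)
  orig <- tidyr::pivot_wider(sim$traces, id_cols = "time_s",
                             names_from = c("region", "channel"),
                             values_from = "value", names_sep = ".")
  keep <- seq(1, nrow(orig), by = 10)
  for (ch in c("M1.astro", "M1.neuron")) {
    got <- rec$value[rec$roi == ch]
    expect_lt(max(abs(got - orig[[ch]][keep])), 0.5)
  }
  # disk round trip stays within the same quantization budget
  tmp <- tempfile(fileext = ".tiff")
  write_frames_tiff(stack$frames, tmp, max_value = 255)
  back <- read_frames_tiff(tmp, max_value = 255)
  expect_lt(max(abs(back - stack$frames)), 0.5)
  unlink(tmp)

  # overlapping layout errors
  bad_layout <- tibble::tibble(name = c("M1.astro", "M1.neuron"),
                               cx = c(20, 22), cy = c(20, 20), r = c(8, 8))
  expect_error(render_fiber_bundle_frames(sim, layout = bad_layout,
                                          width = 48, height = 48),
               "overlap")
})
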