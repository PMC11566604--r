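test_that("threshold detection traces boxcar events exactly", {
  rate <- 30
  z <- rep(0, 20 * rate)
  expect_equal(nrow(suppressWarnings(detect_transients(z, rate))), 0)

  # boxcar z = 3 on [10, 15) s
  z[(10 * rate + 1):(15 * rate)] <- 3
  ev <- suppressWarnings(detect_transients(z, rate, theta_on = 2, theta_off = 0.5))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 10)
  expect_equal(ev$end_s, 15)
  expect_equal(ev$duration_s, 5)
  expect_equal(ev$peak_z, 3)
  expect_equal(ev$peak_s, 10)  # earliest sample on ties

  # two boxcars separated by 0.3 s merge at merge_gap 0.5 s
  z2 <- rep(0, 20 * rate)
  z2[(2 * rate + 1):(4 * rate)] <- 3
  z2[(4.3 * rate + 1):(6 * rate)] <- 3
  ev2 <- suppressWarnings(detect_transients(z2, rate, merge_gap_s = 0.5))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$onset_s, 2)
  expect_equal(ev2$end_s, 6)
  # ... and stay separate when the merge gap is tighter
  ev3 <- suppressWarnings(detect_transients(z2, rate, merge_gap_s = 0.2))
  expect_equal(nrow(ev3), 2)

  expect_warning(detect_transients(z + 5, rate), "z-normalized")
})

test_that("detection agrees with an exhaustive run-length scan on random traces", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(50:2000, 1)
    rate <- sample(c(10, 30), 1)
    # blocky random walks hold thresholds long enough to form events
    z <- cumsum(rnorm(n, 0, 1.5))
    z <- as.numeric(stats::filter(z, rep(1 / 5, 5), sides = 2))
    z[is.na(z)] <- 0
    z <- pmax(pmin(z, 4), -4)
    args <- list(theta_on = runif(1, 1, 3), theta_off = runif(1, 0.1, 0.9),
                 min_dur_s = runif(1, 0.1, 1), merge_gap_s = runif(1, 0, 1))
    got <- suppressWarnings(do.call(detect_transients, c(list(z, rate), args)))
    want <- do.call(brute_detect, c(list(z, rate), args))
    expect_equal(got, want)
  }
})

test_that("transient statistics: frequency, histogram edge at 20 s", {
  ev <- tibble::tibble(onset_s = 1:6, peak_s = 1:6 + 0.5, end_s = 1:6 + 1,
                       peak_z = 3, duration_s = c(5, 10, 19, 21, 30, 25))
  st <- transient_stats(ev, 180)
  expect_equal(st$frequency_per_min, 2)
  expect_equal(st$fraction_over_20s, 0.5)
  expect_true(20 %in% st$histogram$bin_start_s)
  expect_equal(sum(st$histogram$count), 6)

  st0 <- transient_stats(ev[0, ], 60)
  expect_equal(st0$frequency_per_min, 0)
  expect_equal(st0$n_events, 0L)
})

test_that("event-triggered ensembles compute mean, SEM and honor window drops", {
  rate <- 10
  z <- rep(c(1, 3), each = 100)
  # two events with constant windows of 1 and 3 -> mean 2, SEM 1 per bin
  ens <- build_ensemble(z, c(5, 15), rate, pre_s = 2, post_s = 3,
                        rebaseline = FALSE)
  expect_equal(unname(ens$mean), rep(2, 5 * rate))
  expect_equal(unname(ens$sem), rep(1, 5 * rate))

  # single trial: SEM guarded to zero
  e1 <- build_ensemble(z, 5, rate, pre_s = 1, post_s = 1, rebaseline = FALSE)
  expect_true(all(e1$sem == 0))
  expect_equal(nrow(e1$matrix), 1)

  # events without a full window are dropped
  expect_message(e2 <- build_ensemble(z, c(0.05, 5), rate, pre_s = 2, post_s = 3),
                 "dropping 1")
  expect_equal(nrow(e2$matrix), 1)
  expect_error(build_ensemble(z, 0.05, rate, pre_s = 2, post_s = 3),
               "no usable trials")

  # shuffled event times on stationary noise: mean stays near zero
  set.seed(3)
  noise <- rnorm(6000)
  times <- runif(30, 20, 560)
  en <- build_ensemble(noise, times, 10, pre_s = 2, post_s = 5,
                       rebaseline = FALSE)
  expect_lt(max(abs(en$mean)), 3 / sqrt(30))
})

test_that("response metrics recover injected kinetics from noiseless trials", {
  rate <- 30
  cfg <- sim_config()
  astro <- cfg$astro_kinetics
  neuron <- cfg$neuron_kinetics
  n <- 80 * rate
  za <- add_kernel_at(rep(0, n), transient_kernel(astro, rate), 20, rate)
  zn <- add_kernel_at(rep(0, n), transient_kernel(neuron, rate), 20, rate)
  # inject the valley 1.50 s after the astro peak
  tgrid <- (seq_len(n) - 1) / rate
  ctr <- 20 + astro$peak_time_s + 1.50
  zn <- zn - 5 * exp(-(tgrid - ctr)^2 / (2 * 0.3^2))

  ea <- build_ensemble(za, 20, rate, pre_s = 5, post_s = 45)
  en <- build_ensemble(zn, 20, rate, pre_s = 5, post_s = 45)
  ra <- response_metrics(ea, "astro")
  rn <- response_metrics(en, "neuron")
  tol <- 2 / rate
  expect_equal(ra$trials$latency_s, astro$onset_latency_s, tolerance = 0.1)
  expect_equal(ra$trials$peak_time_s, astro$peak_time_s, tolerance = tol)
  expect_equal(rn$trials$latency_s, neuron$onset_latency_s, tolerance = 0.1)
  expect_equal(rn$trials$peak_time_s, neuron$peak_time_s, tolerance = tol)
  expect_equal(ra$trials$duration_s, astro$duration_s, tolerance = 0.5)

  pd <- paired_differences(ra, rn)
  expect_equal(pd$pairs$astro_peak_to_neuron_valley_s, 1.50, tolerance = 0.1)
  # astro later than neuron => positive differences
  expect_gt(pd$pairs$latency_diff_s, 0)
  expect_equal(pd$pairs$latency_diff_s,
               astro$onset_latency_s - neuron$onset_latency_s,
               tolerance = 0.1)

  # flat trial: non-responder; all-flat ensembles error
  flat <- build_ensemble(rep(0, n) + 1e-6 * rnorm(n), 20, rate,
                         pre_s = 5, post_s = 45)
  expect_error(response_metrics(flat, "astro"), "non-responders")
})

test_that("paired differences demand paired inputs and vanish on identical ones", {
  rate <- 30
  z <- add_kernel_at(rep(0, 60 * rate),
                     transient_kernel(sim_config()$neuron_kinetics, rate), 20, rate)
  ens <- build_ensemble(z, 20, rate, pre_s = 5, post_s = 30)
  m1 <- response_metrics(ens, "neuron")
  m2 <- response_metrics(ens, "neuron")
  m2$trials$cell_type <- NULL
  pd <- paired_differences(m1, m2)
  expect_equal(pd$pairs$latency_diff_s, 0)
  expect_equal(pd$pairs$peak_diff_s, 0)

  m3 <- m2
  m3$trials <- m3$trials[c(1, 1), ]
  expect_error(paired_differences(m1, m3), "unpaired")
})

test_that("metrics are invariant to constant shifts absorbed by re-baselining", {
  rate <- 30
  n <- 80 * rate
  set.seed(8)
  z <- add_kernel_at(rnorm(n, 0, 0.1),
                     transient_kernel(sim_config()$astro_kinetics, rate), 20, rate)
  m0 <- response_metrics(build_ensemble(z, 20, rate, 5, 45), "astro")
  m1 <- response_metrics(build_ensemble(z + 2.5, 20, rate, 5, 45), "astro")
  expect_equal(m0$trials$latency_s, m1$trials$latency_s)
  expect_equal(m0$trials$peak_time_s, m1$trials$peak_time_s)
  expect_equal(m0$trials$peak_z, m1$trials$peak_z)
})
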