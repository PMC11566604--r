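# Shared fixtures and oracles, all built in code at test time.

# Small, fast free-behavior config for unit tests.
quick_config <- function(seed = 1, ...) {
  sim_config(duration_s = 300, regions = "M1", seed = seed, ...)
}

# Interval-overlap event matching: a ground-truth event is recalled when some
# detected event overlaps it in time; a detected event is a true positive
# when it overlaps some ground-truth event. Overlapping true events may
# legitimately merge into one detection.
overlap_match <- function(detected, truth) {
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  recall <- mean(vapply(seq_len(nrow(truth)), function(i) {
    any(overlaps(detected$onset_s, detected$end_s,
                 truth$onset_s[i], truth$end_s[i]))
  }, logical(1)))
  precision <- mean(vapply(seq_len(nrow(detected)), function(i) {
    any(overlaps(detected$onset_s[i], detected$end_s[i],
                 truth$onset_s, truth$end_s))
  }, logical(1)))
  list(recall = recall, precision = precision)
}

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

# Place a kernel vector into a trace at time t0 (seconds).
add_kernel_at <- function(x, k, t0, rate_hz) {
  i0 <- round(t0 * rate_hz) + 1L
  idx <- seq_along(k) + i0 - 1L
  keep <- idx >= 1 & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + k[keep]
  x
}

# Brute-force moving-mean oracle (per-window loop).
brute_moving_mean <- function(x, w, align = "center") {
  n <- length(x)
  out <- numeric(n)
  h_left <- if (align == "center") (w - 1L) %/% 2L else w - 1L
  h_right <- if (align == "center") w - 1L - h_left else 0L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h_left)
    hi <- min(n, i + h_right)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Exhaustive run-length transient scan, independent of detect_transients():
# scans every sample, tracks state explicitly, no vectorized shortcuts.
brute_detect <- function(z, rate_hz, theta_on = 2, theta_off = 0.5,
                         min_dur_s = 1, merge_gap_s = 0.5) {
  n <- length(z)
  min_n <- min_dur_s * rate_hz
  # find all seed runs by explicit scan
  seeds <- list()
  i <- 1
  while (i <= n) {
    if (z[i] >= theta_on) {
      j <- i
      while (j < n && z[j + 1] >= theta_on) j <- j + 1
      if (j - i + 1 >= min_n) seeds[[length(seeds) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(seeds) == 0) {
    return(tibble::tibble(onset_s = numeric(), peak_s = numeric(),
                          end_s = numeric(), peak_z = numeric(),
                          duration_s = numeric()))
  }
  ev <- lapply(seeds, function(s) {
    a <- s[1]
    while (a > 1 && z[a - 1] >= theta_off) a <- a - 1
    b <- s[2]
    while (b < n && z[b + 1] >= theta_off) b <- b + 1
    c(a, b)
  })
  ev <- unique(ev)
  ev <- ev[order(vapply(ev, `[`, numeric(1), 1))]
  merged <- list(ev[[1]])
  for (e in ev[-1]) {
    last <- merged[[length(merged)]]
    if ((e[1] - last[2] - 1) / rate_hz < merge_gap_s) {
      merged[[length(merged)]] <- c(last[1], max(last[2], e[2]))
    } else merged[[length(merged) + 1]] <- e
  }
  rows <- lapply(merged, function(e) {
    pk <- e[1] + which.max(z[e[1]:e[2]]) - 1
    tibble::tibble(onset_s = (e[1] - 1) / rate_hz, peak_s = (pk - 1) / rate_hz,
                   end_s = e[2] / rate_hz, peak_z = z[pk],
                   duration_s = (e[2] - e[1] + 1) / rate_hz)
  })
  dplyr::bind_rows(rows)
}

# Spearman via the textbook rank formula with average ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  cor(rx, ry)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# Exact two-sided rank-sum p by enumerating all choose(n+m, n) group
# assignments.
brute_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}
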