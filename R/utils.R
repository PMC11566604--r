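# Internal helpers shared across modules.

# 1-based sample index for a time in seconds (sample i covers [(i-1)/rate, i/rate)).
time_to_sample <- function(t_s, rate_hz) as.integer(round(t_s * rate_hz)) + 1L

sample_to_time <- function(i, rate_hz) (i - 1L) / rate_hz

# Inverse of the cubic smoothstep s(x) = 3x^2 - 2x^3 on [0, 1].
# Steep (infinite-slope) at both ends, which gives the transient kernel its
# sharp onset, peak and termination.
smoothstep_inv <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 - sin(asin(1 - 2 * u) / 3)
}

# Gaussian-smoothed unit-variance noise; `sd_samples` is the smoothing sd.
smooth_noise <- function(n, sd_samples) {
  x <- rnorm(n)
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  y <- stats::filter(x, k, method = "convolution", sides = 2, circular = TRUE)
  y <- as.numeric(y)
  y / sd(y)
}

# Runs of TRUE in a logical vector as a two-column matrix (start, end), 1-based
# inclusive indices.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Population (1/n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
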