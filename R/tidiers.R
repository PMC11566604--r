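# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an event-triggered ensemble into per-bin summaries
#'
#' @param x An `"fp_ensemble"` object.
#' @param ... Unused.
#' @return Tibble: `time_s`, `mean`, `sem`, `n_trials`.
#' @export
tidy.fp_ensemble <- function(x, ...) {
  tibble::tibble(time_s = x$time_s, mean = x$mean, sem = x$sem,
                 n_trials = nrow(x$matrix))
}

#' @rdname tidy.fp_ensemble
#' @export
glance.fp_ensemble <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$matrix), n_dropped = length(x$dropped),
                 pre_s = x$pre_s, post_s = x$post_s, rate_hz = x$rate_hz)
}

#' Tidy a connectivity matrix into long pair rows
#'
#' @param x An `"fp_connectivity"` object.
#' @param ... Unused.
#' @return Tibble: `region_i`, `region_j`, `r`, `state`, `cell_type`
#'   (upper triangle only).
#' @export
tidy.fp_connectivity <- function(x, ...) {
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(region_i = rownames(x$r)[pairs[, 1]],
                 region_j = colnames(x$r)[pairs[, 2]],
                 r = x$r[pairs],
                 state = x$state, cell_type = x$cell_type)
}

#' @rdname tidy.fp_connectivity
#' @export
glance.fp_connectivity <- function(x, ...) {
  tibble::tibble(mean_r = mean_offdiag_r(x), n_regions = nrow(x$r),
                 n_samples = x$n_samples, state = x$state,
                 cell_type = x$cell_type,
                 n_undefined = length(x$undefined))
}

#' Tidy a cross-correlation result
#'
#' @param x An `"fp_crosscorr"` object.
#' @param ... Unused.
#' @return Tibble: `lag_s`, `r`.
#' @export
tidy.fp_crosscorr <- function(x, ...) {
  tibble::tibble(lag_s = x$lags_s, r = x$r_at_lag,
                 state = x$state, region = x$region)
}

#' @rdname tidy.fp_crosscorr
#' @export
glance.fp_crosscorr <- function(x, ...) {
  tibble::tibble(peak_r = x$peak_r, peak_lag_s = x$peak_lag_s,
                 state = x$state, region = x$region, n = x$n)
}

#' Tidy per-trial response metrics
#'
#' @param x An `"fp_metrics"` object.
#' @param ... Unused.
#' @return The per-trial tibble (one row per trial).
#' @export
tidy.fp_metrics <- function(x, ...) x$trials

#' @rdname tidy.fp_metrics
#' @export
glance.fp_metrics <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sem", "n"))
  dplyr::mutate(wide, cell_type = x$cell_type,
                n_trials = nrow(x$trials),
                n_responders = sum(x$trials$responder))
}

#' Glance at a prediction result
#'
#' @param x An `"fp_prediction"` object.
#' @param ... Unused.
#' @return One-row tibble with variance explained and the model/cv spec.
#' @export
glance.fp_prediction <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 region = x$region, state = x$state, n_rows = x$n_rows,
                 model = x$model, cv = x$cv, seed = x$seed)
}

#' @export
print.fp_metrics <- function(x, ...) {
  cat(sprintf("Event-aligned response metrics (%s), %d trials (%d responders)\n",
              x$cell_type, nrow(x$trials), sum(x$trials$responder)))
  print(x$summary)
  invisible(x)
}

#' @export
print.fp_connectivity <- function(x, ...) {
  cat(sprintf("Spearman connectivity (%s, %s), n = %s samples\n",
              x$cell_type, x$state, x$n_samples))
  print(round(x$r, 3))
  invisible(x)
}

#' @export
print.fp_crosscorr <- function(x, ...) {
  cat(sprintf("Astro-neuron cross-correlation (%s, %s): peak r = %.3f at %+.2f s\n",
              x$region, x$state, x$peak_r, x$peak_lag_s))
  invisible(x)
}

#' @export
print.fp_prediction <- function(x, ...) {
  cat(sprintf("Variance explained: %.1f%% (%s, %s; %s, %s)\n",
              100 * x$variance_explained, x$region, x$state, x$model, x$cv))
  invisible(x)
}
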