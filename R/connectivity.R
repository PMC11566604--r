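#' Concatenate state-conditioned samples per region
#'
#' Selects the samples falling inside segments of the requested behavioral
#' state and concatenates them in time order, identically indexed across
#' regions, ready for correlation analysis.
#'
#' @param traces Long tibble with `time_s`, `region`, `z` (one cell type).
#' @param states An `"fp_states"` object or a segments tibble
#'   (`start_s`, `end_s`, `label`).
#' @param state State label to keep (e.g. `"movement"`).
#' @param min_samples Minimum number of retained samples.
#' @return Wide tibble: `time_s` plus one column per region.
#' @export
state_conditioned_series <- function(traces, states, state, min_samples = 300) {
  segs <- if (inherits(states, "fp_states")) states$segments else states
  segs <- segs[segs$label == state, , drop = FALSE]
  wide <- tidyr::pivot_wider(traces, id_cols = "time_s",
                             names_from = "region", values_from = "z")
  keep <- rep(FALSE, nrow(wide))
  for (i in seq_len(nrow(segs))) {
    keep <- keep | (wide$time_s >= segs$start_s[i] - 1e-9 &
                      wide$time_s < segs$end_s[i] - 1e-9)
  }
  out <- wide[keep, , drop = FALSE]
  assert_that(nrow(out) >= min_samples,
              sprintf("state '%s' has %d samples (< %d required)",
                      state, nrow(out), min_samples))
  out
}

#' Inter-regional Spearman correlation matrix
#'
#' Pairwise Spearman rank correlation (average ranks on ties) between the
#' regional series. Constant series give undefined correlations: the affected
#' entries are set to `NA` and flagged with a warning, never silently imputed.
#'
#' @param series Wide tibble from [state_conditioned_series()] (a `time_s`
#'   column is ignored) or a numeric matrix with one column per region.
#' @param state,cell_type Labels stored with the result.
#' @return A list of class `"fp_connectivity"`: `r` (regions x regions
#'   matrix, unit diagonal), `n_samples`, `state`, `cell_type`,
#'   `undefined` (character vector of constant regions).
#' @export
interregion_spearman <- function(series, state = NA_character_,
                                 cell_type = NA_character_) {
  m <- as.matrix(series[, setdiff(colnames(series), "time_s"), drop = FALSE])
  assert_that(ncol(m) >= 2, "at least two regions are required")
  const <- colnames(m)[apply(m, 2, function(v) pop_sd(v) == 0)]
  r <- suppressWarnings(cor(m, method = "spearman"))
  if (length(const) > 0) {
    warning(sprintf("constant series: %s; correlations set to NA",
                    paste(const, collapse = ", ")))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  structure(list(r = r, n_samples = nrow(m), state = state,
                 cell_type = cell_type, undefined = const),
            class = "fp_connectivity")
}

#' Lagged cross-correlation between astrocytic and neuronal signals
#'
#' Pearson correlation of the overlapping segments at every integer-sample
#' lag in `[-max_lag_s, +max_lag_s]`. Positive lag means the astrocytic
#' signal follows the neuronal signal. At `max_lag_s = 0` this reduces to the
#' plain Pearson correlation.
#'
#' @param astro,neuron z-scored traces of equal length.
#' @param rate_hz Sampling rate.
#' @param max_lag_s Maximum lag in seconds (>= 0).
#' @param state,region Labels stored with the result.
#' @return A list of class `"fp_crosscorr"`: `lags_s`, `r_at_lag`, `peak_r`,
#'   `peak_lag_s`, `state`, `region`, `n`.
#' @export
astro_neuron_crosscorr <- function(astro, neuron, rate_hz, max_lag_s = 10,
                                   state = NA_character_,
                                   region = NA_character_) {
  n <- length(astro)
  assert_that(n == length(neuron), "trace lengths differ")
  assert_that(max_lag_s >= 0, "max_lag_s must be >= 0")
  assert_that(pop_sd(astro) > 0 && pop_sd(neuron) > 0,
              "constant input: cross-correlation undefined")
  L <- round(max_lag_s * rate_hz)
  assert_that(L < n, "max lag exceeds the trace length")
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- astro[(1 + k):n]; b <- neuron[1:(n - k)]
    } else {
      a <- astro[1:(n + k)]; b <- neuron[(1 - k):n]
    }
    if (pop_sd(a) == 0 || pop_sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  pk <- which.max(r)
  structure(list(lags_s = lags / rate_hz, r_at_lag = r,
                 peak_r = r[pk], peak_lag_s = lags[pk] / rate_hz,
                 state = state, region = region, n = n),
            class = "fp_crosscorr")
}

#' Connectivity graph with stereotaxic node positions
#'
#' Turns a correlation matrix into an edge list weighted by r, with nodes at
#' the regions' AP/ML coordinates, for spatial network rendering where link
#' thickness encodes correlation strength.
#'
#' @param connectivity An `"fp_connectivity"` object.
#' @param coordinates Tibble `region`, `ap_mm`, `ml_mm`; defaults to
#'   [region_coordinates()].
#' @param width_range Linear map from `|r|` in `[0, 1]` to rendered line
#'   widths, recorded in the result metadata.
#' @return A list of class `"fp_graph"`: `nodes`, `edges` (tibble `from`,
#'   `to`, `weight`, `width`), `state`, `cell_type`, `width_range`.
#' @export
build_graph <- function(connectivity, coordinates = region_coordinates(),
                        width_range = c(0.2, 3)) {
  r <- connectivity$r
  regions <- rownames(r)
  missing <- setdiff(regions, coordinates$region)
  assert_that(length(missing) == 0,
              sprintf("missing coordinates for region(s): %s",
                      paste(missing, collapse = ", ")))
  nodes <- coordinates[match(regions, coordinates$region), ]
  pairs <- utils::combn(regions, 2)
  edges <- tibble::tibble(
    from = pairs[1, ], to = pairs[2, ],
    weight = r[cbind(pairs[1, ], pairs[2, ])])
  edges$width <- width_range[1] + abs(edges$weight) * diff(width_range)
  structure(list(nodes = nodes, edges = edges,
                 state = connectivity$state, cell_type = connectivity$cell_type,
                 width_range = width_range),
            class = "fp_graph")
}

#' Compare a connectivity statistic between two behavioral states
#'
#' Group means with SEM and the appropriate Wilcoxon test: signed-rank for
#' paired values, rank-sum otherwise.
#'
#' @param values_a,values_b Numeric vectors (e.g. per-trial mean r during
#'   movement vs stationary), at least 3 values each.
#' @param paired Whether the values pair up trial-by-trial.
#' @param labels Length-2 group labels.
#' @return A list of class `"fp_contrast"`: `summary` (per-group mean, sem,
#'   n), `test` (a `StatResult` tibble row), `difference` (mean a - mean b).
#' @export
state_contrast <- function(values_a, values_b, paired = FALSE,
                           labels = c("a", "b")) {
  assert_that(length(values_a) >= 3 && length(values_b) >= 3,
              "need at least 3 values per group")
  if (paired) {
    assert_that(length(values_a) == length(values_b),
                "paired groups must have equal lengths")
    test <- wilcoxon_signed_rank(values_a, values_b)
  } else {
    test <- wilcoxon_rank_sum(values_a, values_b)
  }
  summ <- tibble::tibble(
    group = labels,
    mean = c(mean(values_a), mean(values_b)),
    sem = c(sd(values_a) / sqrt(length(values_a)),
            sd(values_b) / sqrt(length(values_b))),
    n = c(length(values_a), length(values_b)))
  structure(list(summary = summ, test = test,
                 difference = mean(values_a) - mean(values_b)),
            class = "fp_contrast")
}

#' Mean off-diagonal correlation of a connectivity matrix
#'
#' @param connectivity An `"fp_connectivity"` object or a square matrix.
#' @return Mean of the upper-triangle entries (NA removed).
#' @export
mean_offdiag_r <- function(connectivity) {
  r <- if (inherits(connectivity, "fp_connectivity")) connectivity$r else connectivity
  mean(r[upper.tri(r)], na.rm = TRUE)
}
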