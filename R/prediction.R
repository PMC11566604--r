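#' Lagged neuronal feature matrix for astrocyte prediction
#'
#' Row t holds the neuronal z-score at `t - lag` for each configured lag.
#' Rows with incomplete history (the first `max(lag)` samples) are dropped,
#' and the returned `target_idx` aligns the remaining rows with the
#' astrocytic target trace.
#'
#' @param neuron_z Neuronal z-scored trace.
#' @param lags_s Lags in seconds (default 0-10 s in 1 s steps).
#' @param rate_hz Sampling rate.
#' @return List: `features` (matrix, one column per lag, named `lag_<s>s`),
#'   `target_idx` (rows of the original trace the features align with).
#' @export
build_lagged_features <- function(neuron_z, lags_s = 0:10, rate_hz = 30) {
  assert_that(length(lags_s) >= 1, "empty lag set")
  lag_n <- round(lags_s * rate_hz)
  n <- length(neuron_z)
  maxlag <- max(lag_n)
  assert_that(maxlag < n, "max lag is not shorter than the trace")
  rows <- (maxlag + 1L):n
  X <- vapply(lag_n, function(k) neuron_z[rows - k], numeric(length(rows)))
  colnames(X) <- sprintf("lag_%gs", lags_s)
  list(features = X, target_idx = rows)
}

#' Variance of astrocytic activity explained by lagged neuronal activity
#'
#' Random-forest regression (100 trees by default) evaluated by blocked
#' cross-validation: the series is cut into contiguous time folds, each fold
#' is predicted by a forest trained on the remaining folds, and variance
#' explained is pooled over the held-out predictions as `1 - SSE/SST`.
#' Contiguous folds avoid the temporal leakage that shuffled cross-validation
#' produces on autocorrelated signals.
#'
#' @param features Feature matrix from [build_lagged_features()] (or the list
#'   it returns).
#' @param target Astrocytic z-scored trace aligned with the feature rows (if
#'   `features` is the list, the full trace - it is subset by `target_idx`).
#' @param n_folds Number of contiguous folds.
#' @param num_trees Trees per forest.
#' @param seed Integer seed (recorded in the result).
#' @param region,state Labels stored with the result.
#' @return A list of class `"fp_prediction"`: `variance_explained`, `region`,
#'   `state`, `n_rows`, `lags`, `model` and `cv` (description strings),
#'   `seed`.
#' @export
fit_variance_explained <- function(features, target, n_folds = 5,
                                   num_trees = 100, seed = 1,
                                   region = NA_character_,
                                   state = NA_character_) {
  if (is.list(features) && !is.data.frame(features)) {
    target <- target[features$target_idx]
    features <- features$features
  }
  X <- as.matrix(features)
  y <- as.numeric(target)
  assert_that(nrow(X) == length(y), "feature rows and target length differ")
  assert_that(nrow(X) >= 10 * ncol(X),
              "need at least 10x more rows than features")
  assert_that(pop_sd(y) > 0, "constant target")
  n <- nrow(X)
  fold_id <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  pred <- numeric(n)
  dat <- data.frame(y = y, X)
  for (f in seq_len(n_folds)) {
    test <- fold_id == f
    fit <- ranger::ranger(y ~ ., data = dat[!test, , drop = FALSE],
                          num.trees = num_trees, seed = seed,
                          num.threads = 1)
    pred[test] <- predict(fit, dat[test, , drop = FALSE],
                          num.threads = 1)$predictions
  }
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(variance_explained = 1 - sse / sst,
                 region = region, state = state,
                 n_rows = n, lags = colnames(X),
                 model = sprintf("ranger random forest, %d trees", num_trees),
                 cv = sprintf("blocked %d-fold (contiguous)", n_folds),
                 seed = seed),
            class = "fp_prediction")
}
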