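#' Wilcoxon signed-rank test for paired two-group comparisons
#'
#' Two-sided signed-rank test on paired differences (or a single difference
#' vector). Zero differences are dropped by the standard convention. The
#' p-value is exact for small samples without ties and uses the normal
#' approximation with tie correction otherwise; the reported Z statistic is
#' the continuity-corrected normal deviate (signed like `mean(d)`).
#'
#' @param x First group, or the paired differences if `y` is `NULL`.
#' @param y Optional second group (paired with `x`).
#' @return A one-row `StatResult` tibble: `test`, `statistic_z`, `p_value`,
#'   `n`, `paired`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    assert_that(length(x) == length(y), "paired groups must have equal lengths")
    x - y
  }
  d <- d[d != 0]
  assert_that(length(d) > 0, "all differences are zero")
  n <- length(d)
  res <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  z <- if (sigma > 0) (v - mu - 0.5 * sign(v - mu)) / sigma else 0
  tibble::tibble(test = "wilcoxon_signed_rank", statistic_z = z,
                 p_value = res$p.value, n = n, paired = TRUE)
}

#' Wilcoxon rank-sum test for unpaired two-group comparisons
#'
#' Two-sided rank-sum (Mann-Whitney) test; exact for small samples without
#' ties, normal approximation with tie correction otherwise. Z is the
#' continuity-corrected normal deviate of the rank-sum statistic.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row `StatResult` tibble.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  assert_that(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  res <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2    # Mann-Whitney U for group a
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt(n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1))))
  z <- if (sigma > 0) (w - mu - 0.5 * sign(w - mu)) / sigma else 0
  tibble::tibble(test = "wilcoxon_rank_sum", statistic_z = z,
                 p_value = res$p.value, n = n1 + n2, paired = FALSE)
}

#' Mean and standard error of the mean
#'
#' `sem = sample sd / sqrt(n)`; a single value yields `sem = 0` with a
#' warning.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble: `mean`, `sem`, `n`.
#' @export
summarize_mean_sem <- function(values) {
  assert_that(length(values) >= 1, "empty input")
  n <- length(values)
  if (n == 1) {
    warning("single value: SEM reported as 0")
    return(tibble::tibble(mean = values, sem = 0, n = 1L))
  }
  tibble::tibble(mean = mean(values), sem = sd(values) / sqrt(n), n = n)
}
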