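#' Two-tailed paired t test on per-subject differences
#'
#' Thin, validated wrapper around [stats::t.test()] for a vector of paired
#' differences: the statistic is `mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom. Differences with zero variance are rejected as
#' degenerate rather than reported with a fabricated p-value.
#'
#' @param diffs Numeric vector of per-subject differences (length >= 2).
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`, `n`.
#' @examples
#' paired_t_test(c(2.1, 1.9, 2.0, 2.2, 1.8, 2.0))
#' @export
paired_t_test <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) abort("need at least 2 paired differences")
  if (anyNA(diffs)) abort("`diffs` contains missing values")
  if (sd(diffs) == 0) {
    abort("degenerate input: all paired differences are identical (zero variance)")
  }
  fit <- t.test(diffs, alternative = "two.sided")
  tibble(
    estimate = unname(fit$estimate),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    n = length(diffs)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in the input
#' order. Wraps [stats::p.adjust()] with validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Minimal detectable paired effect
#'
#' Smallest absolute mean difference `delta` such that a two-tailed paired
#' t test with `n` pairs and within-pair difference standard deviation
#' `sd_diff` reaches the requested power at level `alpha` (noncentral-t
#' computation via [stats::power.t.test()]). At `n = 6`, `alpha = 0.05` and
#' `power = 0.8` the standardized bound `delta / sd_diff` is about 1.43; with
#' `sd_diff = 1.603` the detectable change is |2.3| on the log2 scale.
#'
#' @param n Number of pairs (>= 2).
#' @param sd_diff Standard deviation of the within-pair differences (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power, must exceed `alpha`.
#' @return Single number: the minimal detectable |delta|.
#' @examples
#' detectable_log2fc(n = 6, sd_diff = 1.603)
#' @export
detectable_log2fc <- function(n, sd_diff = 1, alpha = 0.05, power = 0.8) {
  if (n < 2) abort("`n` must be >= 2")
  if (sd_diff <= 0) abort("`sd_diff` must be > 0")
  if (power <= alpha) abort("`power` must exceed `alpha`")
  fit <- power.t.test(n = n, sd = sd_diff, sig.level = alpha, power = power,
                      type = "paired", alternative = "two.sided")
  unname(fit$delta)
}
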