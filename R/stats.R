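#' Strength label for a correlation coefficient
#'
#' |r| > 0.7 is strong, 0.3-0.7 moderate, < 0.3 weak; the boundary
#' points 0.3 and 0.7 fall in the moderate band. The label always uses
#' the absolute value, so strong negative correlations are "STRONG".
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @return `"WEAK"`, `"MODERATE"` or `"STRONG"`.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  if (a > 1 + 1e-12) stop("|r| must be <= 1", call. = FALSE)
  if (a > 0.7) "STRONG" else if (a >= 0.3) "MODERATE" else "WEAK"
}

#' Pearson correlation with strength label
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite, each with
#'   non-zero variance.
#' @return A list of class `correlation_result`: `r`, `p_value`, `n`,
#'   `strength`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, p_value = ct$p.value, n = length(x),
                 strength = correlation_strength(r)),
            class = "correlation_result")
}

#' Two-sample Student's t-test p-value
#'
#' Two-sided; equal-variance Student's test by default, with a Welch
#' option.
#'
#' @param x,y Numeric vectors, n >= 2 each.
#' @param paired Paired test (requires equal lengths).
#' @param welch Use the Welch unequal-variance form.
#' @return Two-sided p-value.
#' @export
two_sample_t <- function(x, y, paired = FALSE, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group", call. = FALSE)
  tt <- stats::t.test(x, y, paired = paired, var.equal = !welch,
                      alternative = "two.sided")
  tt$p.value
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented as (method_a - method_b), i.e. PET-derived
#' minus reference when comparing a PET split-function estimator against
#' scintigraphy. Reports the mean difference, the sample (n - 1) SD,
#' limits of agreement at mean +/- 1.96 SD, and the count of
#' |difference| >= `threshold`.
#'
#' @param method_a,method_b Equal-length numeric vectors, n >= 2.
#' @param threshold Clinically relevant deviation, same units as the
#'   measurements (default 10 percentage points).
#' @return A list of class `agreement_result`: `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `n`, `n_beyond_threshold`,
#'   `threshold`, `differences`.
#' @export
bland_altman <- function(method_a, method_b, threshold = 10) {
  if (length(method_a) != length(method_b))
    stop("methods must have equal length", call. = FALSE)
  if (length(method_a) < 2) stop("need n >= 2", call. = FALSE)
  d <- method_a - method_b
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_difference = m, sd_difference = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         n = length(d), n_beyond_threshold = sum(abs(d) >= threshold),
         threshold = threshold, differences = d),
    class = "agreement_result"
  )
}
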