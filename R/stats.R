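## Cohort statistics: visit-pair changes and monthly rates, pooled-t and
## percentile-bootstrap 95% CIs, Shapiro-Wilk normality gating, Fisher's
## exact test, percent differences.

#' Per-eye visit-pair change and monthly rate
#'
#' difference = visit2 - visit1; rate = difference / (days / monthDays),
#' with one month fixed at 30.44 days.
#'
#' @param v1,v2 measurements at visit 1 and visit 2 (vectorized).
#' @param days inter-visit interval, days (> 0).
#' @param monthDays days per month (default 30.44).
#' @return list(difference, rate_per_month).
#' @export
visitChange <- function(v1, v2, days, monthDays = 30.44) {
  if (any(days <= 0)) stop("days must be > 0")
  d <- v2 - v1
  list(difference = d, rate_per_month = d / (days / monthDays))
}

#' Pooled-variance two-sample t confidence interval
#'
#' Equal-variance Student's t CI for the difference in means
#' (group 1 minus group 2) from summary statistics:
#' \code{sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)}, half-width
#' \code{t(1-alpha/2, n1+n2-2) * sp * sqrt(1/n1 + 1/n2)}.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param level confidence level (default 0.95).
#' @return list(diff, lo, hi, method = "pooled_t", df, n1, n2).
#' @export
pooledTCI <- function(mean1, sd1, n1, mean2, sd2, n2, level = 0.95) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("sd must be >= 0")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  hw <- stats::qt(1 - (1 - level) / 2, df) * sp * sqrt(1 / n1 + 1 / n2)
  d <- mean1 - mean2
  list(diff = d, lo = d - hw, hi = d + hw, method = "pooled_t",
       df = df, n1 = n1, n2 = n2)
}

#' Percentile bootstrap CI for a difference in means
#'
#' Percentile interval of \code{mean(sample1*) - mean(sample2*)} over B
#' paired resamples with replacement (default B = 2000). Seeded and
#' reproducible; the caller's RNG state is untouched.
#'
#' @param sample1,sample2 numeric vectors (non-empty).
#' @param B bootstrap resamples (default 2000; < 100 warns).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (NULL = use current RNG stream).
#' @return list(diff, lo, hi, method = "bootstrap_percentile", B, n1, n2).
#' @export
bootstrapCI <- function(sample1, sample2, B = 2000, level = 0.95, seed = NULL) {
  if (!length(sample1) || !length(sample2)) stop("samples must be non-empty")
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  n1 <- length(sample1); n2 <- length(sample2)
  d <- withSeed(seed, {
    m1 <- colMeans(matrix(sample(sample1, n1 * B, replace = TRUE), n1, B))
    m2 <- colMeans(matrix(sample(sample2, n2 * B, replace = TRUE), n2, B))
    m1 - m2
  })
  a <- (1 - level) / 2
  q <- stats::quantile(d, c(a, 1 - a), names = FALSE, type = 7)
  list(diff = mean(sample1) - mean(sample2), lo = q[1], hi = q[2],
       method = "bootstrap_percentile", B = B, n1 = n1, n2 = n2)
}

#' Choose the CI method by Shapiro-Wilk normality gating
#'
#' Runs the Shapiro-Wilk test on each group (or on pooled mean-centered
#' residuals); if any p-value falls below \code{alpha} the t-interval's
#' normality assumption is considered violated and the percentile bootstrap
#' is selected, otherwise the pooled t.
#'
#' @param sample1,sample2 numeric vectors (n >= 3 each for the test).
#' @param alpha gate level (default 0.05; 0 forces pooled_t).
#' @param mode "per_group" (default) or "pooled_residuals".
#' @return list(method, p_values).
#' @export
normalityGate <- function(sample1, sample2, alpha = 0.05,
                          mode = c("per_group", "pooled_residuals")) {
  mode <- match.arg(mode)
  if (alpha <= 0) return(list(method = "pooled_t", p_values = numeric(0)))
  if (length(sample1) < 3 || length(sample2) < 3)
    stop("Shapiro-Wilk needs n >= 3 per sample")
  p <- if (mode == "per_group") {
    c(stats::shapiro.test(sample1)$p.value, stats::shapiro.test(sample2)$p.value)
  } else {
    stats::shapiro.test(c(sample1 - mean(sample1), sample2 - mean(sample2)))$p.value
  }
  list(method = if (any(p < alpha)) "bootstrap_percentile" else "pooled_t",
       p_values = p)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, at fixed
#' margins, of all tables no more probable than the observed one.
#'
#' @param a,b,c,d cell counts, rows = groups, cols = outcome
#'   (table \code{rbind(c(a, b), c(c, d))}).
#' @return Two-sided p-value.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero table")
  stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))$p.value
}

#' Percent smaller than a reference mean
#'
#' \code{round(100 * (mean_ref - mean_other) / mean_ref)}: by how many
#' percent the second group's mean falls short of the reference group's.
#'
#' @param meanRef reference group mean (> 0).
#' @param meanOther comparison group mean.
#' @return Integer percent.
#' @export
percentSmaller <- function(meanRef, meanOther) {
  if (meanRef <= 0) stop("reference mean must be > 0")
  round(100 * (meanRef - meanOther) / meanRef)
}
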