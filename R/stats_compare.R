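# Statistical layer for the marker-set and group comparisons: normality
# (Shapiro-Wilk), paired t (between-model, MAV), independent t (between
# groups), point-wise significance counting over the normalized gait cycle,
# and the a priori sample-size computation from the noncentral t
# distribution.  Tests are two-sided by default; significance level 0.05.

.as_test_result <- function(statistic, p_value, df, n, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 6),
      ", df = ", signif(x$df, 6), ", p = ", signif(x$p_value, 4),
      " (n = ", paste(x$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, with nonzero variance.
#' @return A `test_result` with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (length(x) > 5000) stop("Shapiro-Wilk supports at most 5000 observations")
  if (stats::sd(x) == 0) stop("Shapiro-Wilk undefined for a zero-variance sample")
  ht <- stats::shapiro.test(x)
  .as_test_result(ht$statistic, ht$p.value, NA_real_, length(x), "Shapiro-Wilk")
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the differences `d = a - b`,
#' df = n - 1, two-sided p.
#'
#' @param a,b Paired numeric samples of equal length n >= 2.
#' @return A `test_result`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t-test requires n >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  .as_test_result(ht$statistic, ht$p.value, ht$parameter, n, "paired t")
}

#' Independent two-sample t-test
#'
#' Pooled-variance (Student) or Welch t, two-sided p.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param equal_var Pooled variance if TRUE (default), Welch otherwise.
#' @return A `test_result`.
#' @export
independent_t <- function(a, b, equal_var = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("independent t-test requires n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples have zero variance: t-test undefined")
  ht <- stats::t.test(a, b, var.equal = equal_var)
  .as_test_result(ht$statistic, ht$p.value, ht$parameter,
                  c(length(a), length(b)),
                  if (equal_var) "independent t (pooled)" else "Welch t")
}

#' Point-wise comparison of normalized gait curves
#'
#' Paired t-test at each of the 101 normalized points across subjects
#' (same subjects under both model conditions), an uncorrected significance
#' mask at `alpha`, and the count of significant points.  Points with
#' zero-variance differences (e.g., identical curves) are non-significant.
#'
#' @param curves_m1,curves_m2 Subject x 101 matrices (or data.frames) of
#'   per-subject curves under the two model conditions; rows (subjects)
#'   must correspond, rownames checked when present on both.
#' @param alpha Significance level, default 0.05.
#' @param adjust Multiple-comparison correction passed to
#'   [stats::p.adjust()]; default `"none"`, matching raw point-count
#'   reporting.
#' @return List of class `pointwise_comparison`: `p_values` (101),
#'   `significant_mask` (101), `n_significant_points`, `alpha`.
#' @export
pointwise_compare <- function(curves_m1, curves_m2, alpha = 0.05,
                              adjust = "none") {
  m1 <- as.matrix(curves_m1); m2 <- as.matrix(curves_m2)
  if (!all(dim(m1) == dim(m2)))
    stop("curve sets must have identical dimensions")
  if (ncol(m1) != 101) stop("curves must have 101 points")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("subject mismatch between model conditions")
  if (nrow(m1) < 2) stop("pointwise comparison requires >= 2 subjects")
  p <- vapply(1:101, function(k) {
    tryCatch(paired_t(m1[, k], m2[, k])$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = adjust)
  mask <- !is.na(p_adj) & p_adj < alpha
  structure(list(p_values = p_adj, significant_mask = mask,
                 n_significant_points = sum(mask), alpha = alpha),
            class = "pointwise_comparison")
}

#' @export
print.pointwise_comparison <- function(x, ...) {
  cat("pointwise comparison: ", x$n_significant_points,
      "/101 points significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

# Power of the independent two-sample t-test (equal groups of size n) at
# effect size d, from the noncentral t distribution.
.t2_power <- function(n, d, alpha, tails) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == 1) {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
}

#' A priori sample size for the independent two-sample t-test
#'
#' Smallest total N (two equal groups, n = N/2 each) whose power from the
#' noncentral t distribution reaches the target, for effect size `d`
#' (Cohen) at significance `alpha`.
#'
#' @param effect_size_d Cohen's d > 0.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param power Target power in (0, 1); default 0.80.
#' @param tails 1 or 2; default 2.
#' @param max_total Search cap on total N; default 1e6.
#' @return Smallest total N (even integer >= 4).
#' @export
power_n_two_sample <- function(effect_size_d, alpha = 0.05, power = 0.80,
                               tails = 2, max_total = 1e6) {
  if (!is.finite(effect_size_d) || effect_size_d <= 0)
    stop("effect size d must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  n <- 2
  while (2 * n <= max_total) {
    if (.t2_power(n, effect_size_d, alpha, tails) >= power)
      return(as.integer(2 * n))
    n <- n + 1
  }
  stop("required sample size exceeds max_total = ", max_total)
}
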