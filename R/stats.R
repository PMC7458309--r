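# Study statistics: rank-sum (Mann-Whitney) group discrimination with
# median/IQR summaries, and Pearson correlation of paired measurements.

iqr_pair <- function(x) unname(stats::quantile(x, c(0.25, 0.75), type = 7))

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Computes the U statistic of the first group from joint mid-ranks and a
#' two-tailed p value: exact (full enumeration of rank assignments, via
#' the exact Wilcoxon distribution) when the smaller group has at most 8
#' observations and there are no ties, otherwise the normal approximation
#' with tie and continuity correction. Groups are summarized as medians
#' with interquartile ranges (quartiles by linear interpolation of order
#' statistics).
#'
#' @param a,b non-empty numeric vectors.
#' @return object of class \code{group_comparison}: \code{u_statistic}
#'   (U of \code{a}), \code{p_two_tailed}, group medians and IQRs, and the
#'   \code{method} used (\code{"exact"} or \code{"normal_approx"}).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(na, nb) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(
    group_a_median = stats::median(a),
    group_b_median = stats::median(b),
    group_iqrs = list(a = iqr_pair(a), b = iqr_pair(b)),
    u_statistic = u_a,
    p_two_tailed = min(wt$p.value, 1),
    method = if (exact) "exact" else "normal_approx"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: medians %.3g [%.3g, %.3g] vs %.3g [%.3g, %.3g]\n",
              x$group_a_median, x$group_iqrs$a[1], x$group_iqrs$a[2],
              x$group_b_median, x$group_iqrs$b[1], x$group_iqrs$b[2]))
  cat(sprintf("  U = %g, two-tailed p = %.4g (%s)\n",
              x$u_statistic, x$p_two_tailed, x$method))
  invisible(x)
}

#' Pearson correlation of paired measurements
#'
#' Product-moment correlation with a two-tailed p value from the
#' t-transform on n - 2 degrees of freedom. The conventional two-tailed
#' 0.05 significance level is reported as a flag only, never used to
#' filter.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return object of class \code{correlation_result}: \code{r}, \code{n},
#'   \code{p_two_tailed}, \code{significant} (p < 0.05).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_two_tailed = ct$p.value,
                 significant = ct$p.value < 0.05),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: r = %.4f (n = %d), two-tailed p = %.4g%s\n",
              x$r, x$n, x$p_two_tailed,
              if (x$significant) " *" else ""))
  invisible(x)
}
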