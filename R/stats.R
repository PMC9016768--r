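#' Statistical tests for end-point comparisons
#'
#' The analysis-stage tests applied to end-point expression data:
#' two-tailed Welch's t-test for comparing conditions expected to differ,
#' one-way ANOVA for conditions expected to be equal, a one-sided
#' one-sample t-test against the ON threshold, and the Grubbs single-
#' outlier test. All return a common `stat_result` record.
#'
#' @param test_name,statistic,df,p_value,alternative,alpha,extra fields of
#'   the record.
#' @return an object of class `stat_result`.
#' @keywords internal
stat_result <- function(test_name, statistic, df, p_value, alternative,
                        alpha = 0.05, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, alternative = alternative,
                   alpha = alpha), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$test_name, sprintf("(%s)\n", x$alternative))
  cat("  statistic:", signif(x$statistic, 6), " df:", signif(x$df, 6),
      " p:", signif(x$p_value, 4), "\n")
  invisible(x)
}

.check_sample <- function(x, name, min_n = 2L) {
  if (length(x) < min_n) {
    stop(name, " needs at least ", min_n, " observations", call. = FALSE)
  }
  if (any(!is.finite(x))) stop(name, " contains non-finite values",
                               call. = FALSE)
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of
#' freedom, used to compare data sets hypothesised to be different.
#'
#' @param a,b numeric samples (>= 2 observations each; at least one with
#'   nonzero variance).
#' @param alpha significance level recorded in the result.
#' @return a `stat_result`.
#' @export
welch_t <- function(a, b, alpha = 0.05) {
  .check_sample(a, "a"); .check_sample(b, "b")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance: Welch statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  stat_result("welch_t", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, "two-sided", alpha)
}

#' One-way analysis of variance
#'
#' Classical pooled-variance one-way ANOVA (F on k-1 and N-k degrees of
#' freedom), used where the hypothesis is that the data sets are equal.
#'
#' @param groups list of >= 2 numeric samples, each with >= 2 observations.
#' @param alpha significance level recorded in the result.
#' @return a `stat_result` with `df` = numerator df and an extra `df2`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("groups must be a list of at least 2 samples", call. = FALSE)
  }
  for (i in seq_along(groups)) .check_sample(groups[[i]], paste0("group ", i))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  stat_result("anova_oneway", unname(ht$statistic),
              unname(ht$parameter[1]), ht$p.value, "two-sided", alpha,
              extra = list(df2 = unname(ht$parameter[2])))
}

#' One-sided one-sample t-test against a threshold
#'
#' Tests whether the sample mean is significantly greater than a given
#' threshold value, as used to call a reaction's mean expression
#' significantly above the 0.5 uM ON level.
#'
#' @param sample numeric sample (>= 2 observations, nonzero variance).
#' @param mu0 threshold value (uM).
#' @param alpha significance level recorded in the result.
#' @return a `stat_result` with alternative `"greater"`.
#' @export
t_greater <- function(sample, mu0, alpha = 0.05) {
  .check_sample(sample, "sample")
  if (stats::var(sample) == 0) {
    stop("sample has zero variance: t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(sample, mu = mu0, alternative = "greater")
  stat_result("t_greater", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, "greater", alpha, extra = list(mu0 = mu0))
}

#' Grubbs single-outlier test
#'
#' Two-sided, single-outlier, non-iterative Grubbs test: computes
#' \eqn{G = \max_i |y_i - \bar{y}| / s} and flags the most extreme point
#' iff G exceeds the critical value
#' \deqn{\frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n - 2 + t^2}}, \quad
#'       t = t_{\alpha/(2n),\, n-2},}
#' derived from the t-distribution. At most one point is flagged per
#' call. A zero-variance sample yields no outlier (G undefined, flagged
#' in the result).
#'
#' @param sample numeric sample (>= 3 observations).
#' @param alpha significance level, default 0.05.
#' @return list with `outlier_index` (integer or `NA`) and `result`
#'   (a `stat_result`; extra fields `critical`, `g_defined`).
#' @export
grubbs <- function(sample, alpha = 0.05) {
  .check_sample(sample, "sample", min_n = 3L)
  n <- length(sample)
  s <- stats::sd(sample)
  if (s == 0) {
    return(list(outlier_index = NA_integer_,
                result = stat_result("grubbs", NA_real_, n - 2, NA_real_,
                                     "two-sided", alpha,
                                     extra = list(critical = grubbs_critical(n, alpha),
                                                  g_defined = FALSE))))
  }
  dev <- abs(sample - mean(sample))
  idx <- which.max(dev)
  G <- dev[idx] / s
  crit <- grubbs_critical(n, alpha)
  # p-value: invert the critical-value relation back to a t tail probability
  t2 <- (G^2 * n * (n - 2)) / ((n - 1)^2 - G^2 * n)
  p <- if (t2 < 0) 0 else
    min(1, 2 * n * stats::pt(sqrt(t2), df = n - 2, lower.tail = FALSE))
  list(outlier_index = if (G > crit) idx else NA_integer_,
       result = stat_result("grubbs", G, n - 2, p, "two-sided", alpha,
                            extra = list(critical = crit, g_defined = TRUE)))
}

#' Grubbs critical value
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return two-sided single-outlier critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Apply a named test across a grouped endpoints table
#'
#' Batch interface: runs one test per declared comparison over an
#' end-point table and returns one result row per comparison. Comparisons
#' are declared explicitly as condition labels (the pairing behind any
#' particular figure's annotations is the caller's choice).
#'
#' @param endpoints end-point table with `condition` and `endpoint_uM`.
#' @param comparisons list of comparisons; each element is a list with
#'   `test` (`"welch_t"`, `"anova_oneway"`, `"t_greater"`, `"grubbs"`),
#'   `conditions` (character vector of condition labels) and, for
#'   `t_greater`, `mu0`.
#' @param alpha significance level.
#' @return data.frame with one row per comparison: `test`, `conditions`,
#'   `statistic`, `df`, `p_value`, `significant`, `outlier_index`.
#' @export
batch_tests <- function(endpoints, comparisons, alpha = 0.05) {
  grab <- function(cond) endpoints$endpoint_uM[endpoints$condition == cond]
  rows <- lapply(comparisons, function(cmp) {
    samples <- lapply(cmp$conditions, grab)
    out_idx <- NA_integer_
    r <- switch(cmp$test,
      welch_t = welch_t(samples[[1]], samples[[2]], alpha),
      anova_oneway = anova_oneway(samples, alpha),
      t_greater = t_greater(samples[[1]], cmp$mu0, alpha),
      grubbs = {
        g <- grubbs(samples[[1]], alpha)
        out_idx <- g$outlier_index
        g$result
      },
      stop("unknown test: ", cmp$test, call. = FALSE))
    data.frame(test = cmp$test,
               conditions = paste(cmp$conditions, collapse = " vs "),
               statistic = r$statistic, df = r$df, p_value = r$p_value,
               significant = !is.na(r$p_value) && r$p_value < alpha,
               outlier_index = out_idx)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
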