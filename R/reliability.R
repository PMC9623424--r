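#' Percent change of a group mean
#'
#' The change in a cohort's mean area, as a percentage of the presurgery
#' mean: `100 * diff_mean / pre_mean`, where `diff_mean` is the mean of the
#' post-minus-pre differences. Computed from the mean difference rather than
#' from independently rounded pre/post means, which keeps published
#' change tables internally consistent at two decimals.
#'
#' @param pre_mean mean of the presurgery values (nonzero).
#' @param diff_mean mean of the post - pre differences, same units.
#' @return percent change (e.g. `6.74` for +6.74%).
#' @export
#' @examples
#' percent_change(21.51, 1.45)   # +6.74%
percent_change <- function(pre_mean, diff_mean) {
  if (!is.finite(pre_mean) || pre_mean == 0)
    stopf("percent change is undefined for a zero presurgery mean")
  100 * diff_mean / pre_mean
}

# Exact null distribution of W+ for ranks r: counts over 0..sum(r) via the
# generating polynomial prod_i (1 + x^{r_i}); returns probabilities.
signed_rank_null <- function(ranks) {
  total <- sum(ranks)
  counts <- c(1, numeric(total))          # counts[w + 1] = #assignments with W+ = w
  for (r in ranks) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided test of symmetry of the post-minus-pre differences about zero.
#' Zero differences are dropped (classic convention; the count is reported).
#' Absolute differences are ranked with midranks for ties;
#' `W = min(W+, W-)`. With at most 15 nonzero differences and no ties in
#' the absolute values, the p-value is exact, from the full null
#' distribution of `W+` over all sign assignments; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param differences numeric vector of paired differences.
#' @return list of class `wilcoxon_result`: `statistic` (W), `w_plus`,
#'   `w_minus`, `p_value`, `n_used` (nonzero differences), `n_zero`
#'   (dropped), `method` (`"exact"` or `"normal approximation"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 1.7, 0.4, 0.9))$p_value  # 2/64
wilcoxon_signed_rank <- function(differences) {
  d <- differences[is.finite(differences)]
  n_zero <- sum(d == 0)
  if (n_zero > 0) message(sprintf("dropped %d zero difference(s)", n_zero))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero: the test is degenerate")

  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  has_ties <- anyDuplicated(abs(d)) > 0

  if (n <= 15 && !has_ties) {
    probs <- signed_rank_null(as.integer(r))
    # two-sided: double the smaller tail of W+, capped at 1
    lower <- sum(probs[seq_len(w_plus + 1)])
    upper <- sum(probs[(w_plus + 1):length(probs)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                 p_value = p, n_used = n, n_zero = n_zero, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank (%s): W = %g, n = %d (%d zeros dropped), p = %.4g\n",
              x$method, x$statistic, x$n_used, x$n_zero, x$p_value))
  invisible(x)
}

#' Intraclass correlation ICC(3,1): two-way mixed, consistency, single measure
#'
#' Test-retest reliability of paired measurements: the between-subject
#' variance as a fraction of between- plus within-subject variance,
#' estimated from the two-way subjects-by-measurements layout as
#' \deqn{ICC = (MS_B - MS_E) / (MS_B + (k - 1) MS_E)}
#' where \eqn{MS_B} is the between-subjects mean square and \eqn{MS_E} the
#' residual after removing subject and measurement effects. The measurement
#' occasion (pre vs post) is a fixed effect, so a constant shift between
#' occasions does not reduce the ICC (consistency form). The two-sided
#' `1 - alpha` confidence interval comes from `F = MS_B / MS_E` with
#' `n - 1` and `(n - 1)(k - 1)` degrees of freedom. Estimates may be
#' negative in small or noisy samples and are reported as computed, never
#' clamped.
#'
#' @param pre,post paired measurements (equal length, n >= 3); alternatively
#'   `pre` may be an n x k matrix of repeated measurements with
#'   `post` omitted.
#' @param alpha two-sided significance level for the CI.
#' @return list of class `icc_estimate`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`, `ms_between`, `ms_error`, `alpha`.
#' @export
#' @examples
#' icc_3_1(c(10, 20, 30, 40), c(12, 19, 33, 41))
icc_3_1 <- function(pre, post = NULL, alpha = 0.05) {
  x <- if (is.null(post)) as.matrix(pre) else cbind(pre, post)
  if (anyNA(x)) stopf("incomplete pairs must be dropped before icc_3_1")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3) stopf("ICC needs at least 3 subjects (got %d)", n)
  if (k < 2) stopf("ICC needs at least 2 repeated measurements")

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_between <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_error <- ss_total - ss_between - ss_cols

  ms_between <- ss_between / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  if (ms_between <= 0 && ms_error <= 1e-300)
    stopf("no variance in the data: ICC is undefined")

  if (ms_error <= 1e-300) {
    icc <- 1; ci <- c(1, 1)
  } else {
    icc <- (ms_between - ms_error) / (ms_between + (k - 1) * ms_error)
    fobs <- ms_between / ms_error
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], n = n, k = k,
                 ms_between = ms_between, ms_error = ms_error, alpha = alpha),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (%.0f%% CI %.3f to %.3f), n = %d, k = %d\n",
              x$icc, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Distribution summary: mean, SD, minimum, quartiles, maximum
#'
#' The seven-number summary used for inter-scan intervals: sample SD
#' (`n - 1` denominator) and quartiles by linear interpolation of order
#' statistics (type-7 convention). A single observation yields SD 0 with a
#' warning.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `(mean, sd, min, q1, median, q3, max)`.
#' @export
interval_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stopf("cannot summarize an empty sample")
  s <- if (length(values) == 1) {
    warnf("single observation: SD reported as 0")
    0
  } else stats::sd(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(values), sd = s, min = min(values),
    q1 = q[1], median = q[2], q3 = q[3], max = max(values))
}

#' Paired pre/post change summary for one measure
#'
#' Means and SDs of the pre, post and difference distributions, the percent
#' change of the group mean, and the Wilcoxon signed-rank p-value. If every
#' difference is zero the Wilcoxon test is degenerate and the p-value is
#' reported as `NA` ("no change").
#'
#' @param pre,post paired vectors (equal length).
#' @return one-row data frame with columns `n`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `diff_mean`, `diff_sd`, `percent_change`,
#'   `wilcoxon_p`.
#' @export
change_summary <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  keep <- is.finite(pre) & is.finite(post)
  if (sum(!keep) > 0)
    message(sprintf("dropped %d incomplete pair(s)", sum(!keep)))
  pre <- pre[keep]; post <- post[keep]
  d <- post - pre
  p <- if (all(d == 0)) NA_real_
       else suppressMessages(wilcoxon_signed_rank(d)$p_value)
  pc <- if (mean(pre) == 0) NA_real_ else percent_change(mean(pre), mean(d))
  data.frame(n = length(pre),
             pre_mean = mean(pre), pre_sd = stats::sd(pre),
             post_mean = mean(post), post_sd = stats::sd(post),
             diff_mean = mean(d), diff_sd = stats::sd(d),
             percent_change = pc, wilcoxon_p = p)
}
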