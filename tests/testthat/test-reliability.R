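test_that("percent change reproduces the published change column", {
  ref <- reference_change_table()
  # every component whose printed pre-mean and difference are internally
  # consistent with the printed percent change at two decimals
  for (comp in c("SAT", "IMAT", "VAT", "VLDM", "LDM", "HDM", "VHDM",
                 "TAT", "TSM")) {
    row <- ref[ref$component == comp, ]
    expect_equal(round(percent_change(row$pre_mean, row$diff_mean), 2),
                 row$percent_change,
                 info = comp)
  }
  expect_equal(percent_change(5, 0), 0)
  expect_error(percent_change(0, 1), "zero presurgery mean")
})

test_that("Wilcoxon p matches exhaustive sign-assignment enumeration", {
  set.seed(31)
  for (n in c(4, 6, 8, 10, 12)) {
    for (rep in 1:4) {
      d <- round(stats::rnorm(n), 4)
      mine <- suppressMessages(wilcoxon_signed_rank(d))
      expect_equal(mine$p_value, wilcoxon_enumeration_p(d),
                   tolerance = 1e-12)
    }
  }
  # all-positive n = 6, no ties: exact two-sided p = 2/64
  res <- suppressMessages(wilcoxon_signed_rank(c(0.5, 1, 1.5, 2, 2.5, 3)))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
})

test_that("Wilcoxon agrees with wilcox.test in both regimes", {
  set.seed(57)
  d_exact <- rnorm(11)
  expect_equal(suppressMessages(wilcoxon_signed_rank(d_exact))$p_value,
               wilcox.test(d_exact, exact = TRUE)$p.value)
  d_big <- rnorm(40)
  expect_equal(suppressMessages(wilcoxon_signed_rank(d_big))$p_value,
               wilcox.test(d_big, exact = FALSE, correct = TRUE)$p.value)
  d_ties <- c(1, 1, -1, 2, 2, 3, -2, 4, 5, -3, 3, 6, -6, 2, 1, 4)
  expect_equal(suppressMessages(wilcoxon_signed_rank(d_ties))$p_value,
               wilcox.test(d_ties, exact = FALSE, correct = TRUE)$p.value)
})

test_that("Wilcoxon invariances: symmetry, positive scaling, sign flip", {
  set.seed(19)
  d <- rnorm(7)
  anti <- c(d, -d)   # antisymmetric sample: W+ = W-
  res <- suppressMessages(wilcoxon_signed_rank(anti))
  expect_equal(res$w_plus, res$w_minus)
  expect_equal(res$p_value, 1, tolerance = 1e-8)

  p0 <- suppressMessages(wilcoxon_signed_rank(d))$p_value
  expect_equal(suppressMessages(wilcoxon_signed_rank(3.7 * d))$p_value, p0)
  expect_equal(suppressMessages(wilcoxon_signed_rank(-d))$p_value, p0)
  expect_gt(p0, 0)
  expect_lte(p0, 1)
})

test_that("zeros are dropped and an all-zero sample is degenerate", {
  expect_message(res <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3)),
                 "2 zero difference")
  expect_equal(res$n_used, 3)
  expect_equal(res$n_zero, 2)
  expect_error(suppressMessages(wilcoxon_signed_rank(c(0, 0))), "degenerate")
})

test_that("ICC(3,1) matches the two-way ANOVA oracle on random tables", {
  set.seed(23)
  for (rep in 1:100) {
    pre <- rnorm(10, 50, 10)
    post <- pre * runif(1, 0.5, 1.5) + rnorm(10, 0, runif(1, 0.1, 10))
    expect_equal(icc_3_1(pre, post)$icc, icc31_aov_oracle(pre, post),
                 tolerance = 1e-10)
  }
})

test_that("ICC is 1 exactly for identical and constant-offset pairs", {
  x <- c(10, 20, 30, 40, 55)
  expect_equal(icc_3_1(x, x)$icc, 1)
  est <- icc_3_1(x, x + 7)
  expect_equal(est$icc, 1)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
})

test_that("ICC degenerate and small-sample errors are explicit", {
  expect_error(icc_3_1(c(1, 1, 1), c(1, 1, 1)), "no variance")
  expect_error(icc_3_1(c(1, 2), c(1, 2)), "at least 3 subjects")
})

test_that("ICC may be negative and the CI always brackets the estimate", {
  set.seed(83)
  seen_negative <- FALSE
  for (rep in 1:50) {
    pre <- rnorm(8, 100, 1)
    post <- rnorm(8, 100, 30)    # within-noise dwarfs between-variance
    est <- icc_3_1(pre, post)
    expect_lte(est$ci_low, est$icc + 1e-12)
    expect_gte(est$ci_high, est$icc - 1e-12)
    expect_lte(est$icc, 1)
    if (est$icc < 0) seen_negative <- TRUE
  }
  expect_true(seen_negative)
})

test_that("ICC confidence intervals cover the true ICC at nominal rate", {
  n_rep <- 300
  hits <- vapply(seq_len(n_rep), function(r) {
    cs <- paired_cohort_spec(n_patients = 50, mean_areas = c(SAT = 300),
                             sigma_between = 30, sigma_within = 10,
                             seed = 40000 + r)
    co <- generate_paired_cohort(cs)
    est <- icc_3_1(co$pre, co$post)
    est$ci_low <= 0.9 && 0.9 <= est$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("interval_summary follows the documented conventions", {
  s <- interval_summary(c(1, 2, 3, 4, 5))
  expect_equal(unname(s[c("median", "q1", "q3")]), c(3, 2, 4))
  expect_equal(unname(s[c("min", "max")]), c(1, 5))
  expect_warning(s1 <- interval_summary(7), "single observation")
  expect_equal(unname(s1["mean"]), 7)
  expect_equal(unname(s1["sd"]), 0)
  expect_error(interval_summary(numeric(0)), "empty")
  set.seed(11)
  z <- interval_summary(rnorm(1000))
  expect_lt(abs(z[["mean"]]), 0.1)
  expect_lt(abs(z[["sd"]] - 1), 0.1)
})

test_that("change_summary ties the pieces together", {
  set.seed(3)
  pre <- rnorm(20, 100, 10)
  post <- pre + rnorm(20, 2, 3)
  cs <- change_summary(pre, post)
  expect_equal(cs$diff_mean, cs$post_mean - cs$pre_mean)
  expect_equal(cs$percent_change, 100 * cs$diff_mean / cs$pre_mean)
  expect_true(is.na(change_summary(pre, pre)$wilcoxon_p))
})
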