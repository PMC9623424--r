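test_that("theoretical ICC is the between/(between+within) variance ratio", {
  expect_equal(theoretical_icc(paired_cohort_spec(sigma_between = 1,
                                                  sigma_within = 0)), 1)
  expect_equal(theoretical_icc(paired_cohort_spec(sigma_between = 0,
                                                  sigma_within = 1)), 0)
  expect_equal(theoretical_icc(paired_cohort_spec(sigma_between = 3,
                                                  sigma_within = 1)), 0.9)
  expect_equal(theoretical_icc(paired_cohort_spec(sigma_between = 30,
                                                  sigma_within = 10)), 0.9)
  expect_error(theoretical_icc(paired_cohort_spec(sigma_between = 0,
                                                  sigma_within = 0)),
               "undefined")
})

test_that("zero within-patient variance makes pre equal post and ICC 1", {
  cs <- paired_cohort_spec(n_patients = 12, mean_areas = c(SAT = 300),
                           sigma_between = 40, sigma_within = 0, seed = 3)
  co <- generate_paired_cohort(cs)
  expect_equal(co$pre, co$post)
  expect_equal(icc_3_1(co$pre, co$post)$icc, 1)
})

test_that("cohort simulation is deterministic and respects its spec", {
  cs <- paired_cohort_spec(n_patients = 10, seed = 42)
  a <- suppressWarnings(generate_paired_cohort(cs))
  b <- suppressWarnings(generate_paired_cohort(cs))
  expect_identical(a, b)
  expect_equal(nrow(a), 10 * length(cs$mean_areas))
  expect_true(all(a$pre >= 0 & a$post >= 0))
  expect_true(all(a$interval_days >= 1))
  expect_true(all(a$pre_date <= a$surgery_date & a$surgery_date <= a$post_date))
})

test_that("negative area draws are truncated at zero with a warning", {
  cs <- paired_cohort_spec(n_patients = 30, mean_areas = c(VHDM = 3),
                           sigma_between = 30, sigma_within = 5, seed = 8)
  expect_warning(co <- generate_paired_cohort(cs), "truncated")
  expect_true(any(co$pre == 0 | co$post == 0))
})

test_that("systematic shift moves post but not pre", {
  base <- paired_cohort_spec(n_patients = 40, mean_areas = c(SAT = 300),
                             sigma_between = 10, sigma_within = 1, seed = 5)
  shifted <- paired_cohort_spec(n_patients = 40, mean_areas = c(SAT = 300),
                                sigma_between = 10, sigma_within = 1,
                                systematic_shift = 25, seed = 5)
  a <- generate_paired_cohort(base)
  b <- generate_paired_cohort(shifted)
  expect_equal(a$pre, b$pre)
  expect_equal(b$post - a$post, rep(25, 40))
})

test_that("ICC estimates recover the theoretical ICC over replicates", {
  # Monte-Carlo over replicate cohorts at the spec's own study conditions.
  n_rep <- 200
  cs0 <- paired_cohort_spec(n_patients = 50, mean_areas = c(SAT = 300),
                            sigma_between = 30, sigma_within = 10)
  target <- theoretical_icc(cs0)
  iccs <- vapply(seq_len(n_rep), function(r) {
    cs <- paired_cohort_spec(n_patients = 50, mean_areas = c(SAT = 300),
                             sigma_between = 30, sigma_within = 10,
                             seed = 9000 + r)
    co <- generate_paired_cohort(cs)
    icc_3_1(co$pre, co$post)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - target), 0.02)
})
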