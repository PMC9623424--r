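test_that("the same HU maps to SAT, IMAT or VAT depending on compartment", {
  hu <- matrix(-100L, 2, 2)
  comp <- matrix(c(COMPARTMENTS[["subcutaneous"]], COMPARTMENTS[["muscular"]],
                   COMPARTMENTS[["visceral"]], COMPARTMENTS[["background"]]),
                 2, 2)
  slice <- ct_slice(hu, 1)
  labels <- segment_tissues(slice, compartment_map(comp, slice))
  lab <- matrix(as.character(tissue_of(labels)), 2, 2)
  expect_equal(lab[1, 1], "SAT")
  expect_equal(lab[2, 1], "IMAT")
  expect_equal(lab[1, 2], "VAT")
  expect_equal(lab[2, 2], "unclassified")
})

test_that("visceral fat outside the narrower VAT window stays unclassified", {
  hu <- matrix(c(-170L, -151L, -150L, -50L, -49L, -30L), 1)
  comp <- matrix(COMPARTMENTS[["visceral"]], 1, 6)
  slice <- ct_slice(hu, 1)
  lab <- as.character(tissue_of(segment_tissues(slice, compartment_map(comp))))
  expect_equal(lab, c("unclassified", "unclassified", "VAT", "VAT",
                      "unclassified", "unclassified"))
})

test_that("segmentation agrees with a per-pixel brute-force oracle", {
  sch <- default_threshold_scheme()
  set.seed(101)
  for (rep in 1:25) {
    hu <- matrix(sample(-300:300, 32 * 32, replace = TRUE), 32, 32)
    comp <- matrix(sample(unname(COMPARTMENTS), 32 * 32, replace = TRUE),
                   32, 32)
    slice <- ct_slice(hu, 1)
    mine <- unclass(segment_tissues(slice, compartment_map(comp), sch))
    attr(mine, "tissues") <- NULL
    oracle <- segment_brute_force(slice$pixels, comp, sch)
    expect_identical(mine, oracle)
  }
})

test_that("labels partition the labeled set and are compartment-exclusive", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 12, noise_sd = 3))
  labels <- unclass(segment_tissues(ph$slice, ph$compartments))
  counts <- tabulate(labels + 1L, nbins = length(TISSUE_CLASSES) + 1L)
  expect_equal(sum(counts), length(labels))
  # adipose labels never appear outside their compartment
  expect_true(all(ph$compartments$labels[labels == 1L] ==
                    COMPARTMENTS[["subcutaneous"]]))
  expect_true(all(ph$compartments$labels[labels == 2L] ==
                    COMPARTMENTS[["muscular"]]))
  expect_true(all(ph$compartments$labels[labels == 3L] ==
                    COMPARTMENTS[["visceral"]]))
})

test_that("enlarging a class's interval never shrinks its area", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 14, noise_sd = 3))
  base <- default_threshold_scheme()
  wide <- base
  wide$lo[wide$tissue == "VAT"] <- -190L
  wide$hi[wide$tissue == "VAT"] <- -30L
  a0 <- compute_areas(segment_tissues(ph$slice, ph$compartments, base),
                      ph$slice)$areas[["VAT"]]
  a1 <- compute_areas(segment_tissues(ph$slice, ph$compartments, wide),
                      ph$slice)$areas[["VAT"]]
  expect_gte(a1, a0)
})

test_that("areas convert pixel counts with the physical pixel area", {
  hu <- matrix(-1000L, 40, 40)
  hu[1:25, 1:40] <- -100L   # 1000 subcutaneous fat pixels
  comp <- matrix(COMPARTMENTS[["background"]], 40, 40)
  comp[1:25, 1:40] <- COMPARTMENTS[["subcutaneous"]]
  slice <- ct_slice(hu, 1)
  res <- compute_areas(segment_tissues(slice, compartment_map(comp, slice)),
                       slice)
  expect_equal(res$areas[["SAT"]], 10)
  expect_equal(res$tat_cm2, 10)
  expect_equal(res$tsm_cm2, 0)

  # doubling the spacing quadruples every area for the same label map
  slice2 <- ct_slice(hu, 2)
  res2 <- compute_areas(segment_tissues(slice2, compartment_map(comp, slice2)),
                        slice2)
  expect_equal(res2$areas, 4 * res$areas)

  # empty label map: everything zero
  empty <- ct_slice(matrix(-1000L, 8, 8), 1)
  res0 <- compute_areas(segment_tissues(empty,
                                        compartment_map(matrix(0L, 8, 8))),
                        empty)
  expect_true(all(res0$areas == 0) && res0$tat_cm2 == 0 && res0$tsm_cm2 == 0)
})

test_that("TAT and TSM are exact sums of their components", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 21, noise_sd = 3))
  res <- compute_areas(segment_tissues(ph$slice, ph$compartments), ph$slice)
  expect_identical(res$tat_cm2, sum(res$areas[c("SAT", "IMAT", "VAT")]))
  expect_identical(res$tsm_cm2,
                   sum(res$areas[c("VLDM", "LDM", "NDM", "HDM", "VHDM")]))
})
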