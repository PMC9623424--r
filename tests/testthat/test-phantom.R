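test_that("phantom spec validation rejects impossible geometry", {
  expect_error(phantom_spec(body_axes = c(120, 92)), "fascia")
  expect_error(phantom_spec(fascia_axes = c(95, 70)), "cavity")
  expect_error(phantom_spec(image_size = 128L, pixel_spacing = 1),
               "field of view")
  expect_error(phantom_spec(vat_fraction = 1), "vat_fraction")
  expect_error(phantom_spec(muscle_class_mix = c(VLDM = 0.5, LDM = 0.5,
                                                 NDM = 0, HDM = 0.1,
                                                 VHDM = 0)),
               "sum to 1")
  expect_error(phantom_spec(hu_means = default_hu_means(c(SAT = -30))),
               "strictly inside")
})

test_that("empty blob fractions give zero IMAT and VAT ground truth", {
  ph <- generate_l3_phantom(small_phantom_spec(imat_fraction = 0,
                                               vat_fraction = 0, seed = 5))
  expect_identical(ph$truth$areas[["IMAT"]], 0)
  expect_identical(ph$truth$areas[["VAT"]], 0)
  expect_gt(ph$truth$areas[["SAT"]], 0)
})

test_that("zero-noise phantom segments back to ground truth pixel for pixel", {
  ph <- generate_l3_phantom(small_phantom_spec(noise_sd = 0, seed = 9))
  labels <- segment_tissues(ph$slice, ph$compartments)
  for (t in TISSUE_CLASSES) {
    code <- match(t, TISSUE_CLASSES)
    truth_px <- ph$tissue_map == PHANTOM_TISSUE_CODES[[t]]
    expect_identical(unclass(labels) == code, truth_px)
  }
  res <- compute_areas(labels, ph$slice)
  expect_equal(res$areas, ph$truth$areas, tolerance = 0)
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_l3_phantom(small_phantom_spec(seed = 123))
  b <- generate_l3_phantom(small_phantom_spec(seed = 123))
  expect_identical(a$slice$pixels, b$slice$pixels)
  expect_identical(a$tissue_map, b$tissue_map)
  c <- generate_l3_phantom(small_phantom_spec(seed = 124))
  expect_false(identical(a$slice$pixels, c$slice$pixels))
})

test_that("ground-truth labels conserve the total field-of-view area", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 4))
  px_area <- prod(ph$slice$pixel_spacing)
  total_cm2 <- length(ph$tissue_map) * px_area / 100
  all_labels_cm2 <- sum(table(ph$tissue_map)) * px_area / 100
  expect_equal(all_labels_cm2, total_cm2)
  seg_plus_rest <- sum(ph$truth$areas) +
    sum(ph$tissue_map %in% PHANTOM_TISSUE_CODES[c("AIR", "ORGAN", "BONE")]) *
      px_area / 100
  expect_equal(seg_plus_rest, total_cm2)
  expect_equal(sum(ph$truth$areas[c("SAT", "IMAT", "VAT")]),
               ph$truth$areas[["SAT"]] + ph$truth$areas[["IMAT"]] +
                 ph$truth$areas[["VAT"]])
})

test_that("phantom generation leaves the caller's RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  generate_l3_phantom(small_phantom_spec(seed = 1))
  expect_identical(.Random.seed, before)
})
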