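test_that("HU conversion is exact at the standard CT rescale", {
  # stored 0 with slope 1 / intercept -1024 is air; stored 1124 is 100 HU
  px <- matrix(c(-1024L, 100L, 0L, 3071L), 2, 2)
  slice <- ct_slice(px, pixel_spacing = 0.8, patient_id = "X")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(slice, path)
  back <- read_ct_slice(path)
  expect_identical(back$pixels, slice$pixels)
  expect_equal(back$pixel_spacing, c(0.8, 0.8))
  expect_identical(back$patient_id, "X")
})

test_that("a written phantom reads back bit-identical with its metadata", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 2),
                            patient_id = "P001",
                            acquisition_date = as.Date("2019-02-28"))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir, stem = "p001")
  back <- read_ct_slice(paths[["dicom"]])
  expect_identical(back$pixels, ph$slice$pixels)
  expect_identical(back$acquisition_date, as.Date("2019-02-28"))
  cmap <- read_compartment_map(paths[["compartments"]], back)
  expect_identical(cmap$labels, ph$compartments$labels)
  tmap <- read_tissue_raster(paths[["tissues"]], back)
  expect_identical(tmap, ph$tissue_map)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(unlist(truth$areas_cm2), ph$truth$areas)
})

test_that("the DICOM writer is readable by an independent implementation", {
  # pydicom, via the system python, as the external oracle
  py <- Sys.which("python")
  skip_if(py == "", "no python on PATH")
  ph <- generate_l3_phantom(
    phantom_spec(image_size = 64L, pixel_spacing = 4, body_axes = c(100, 80),
                 fascia_axes = c(75, 60), cavity_axes = c(55, 45),
                 vertebra_radius = 15, seed = 6))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(ph$slice, path)
  script <- paste(
    "import pydicom, numpy as np, sys",
    sprintf("d = pydicom.dcmread(r'%s')", path),
    "hu = d.pixel_array * float(d.RescaleSlope) + float(d.RescaleIntercept)",
    "print(int(hu.sum()), hu.shape[0], hu.shape[1],",
    "      float(d.PixelSpacing[0]), d.PatientID)",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out, " +")[[1]]
  expect_equal(as.numeric(parts[1]), sum(ph$slice$pixels))
  expect_equal(as.integer(parts[2:3]), dim(ph$slice$pixels))
  expect_equal(as.numeric(parts[4]), 4)
})

test_that("label rasters with unknown codes or wrong shape are rejected", {
  dir <- withr::local_tempdir()
  bad <- matrix(c(0L, 250L), 2, 2)
  p <- file.path(dir, "bad.png")
  png::writePNG(bad / 255, p)
  expect_error(read_compartment_map(p), "250")

  ok <- matrix(0L, 4, 4)
  p2 <- file.path(dir, "ok.png")
  png::writePNG(ok / 255, p2)
  m <- read_compartment_map(p2)
  expect_equal(sum(m$labels != 0), 0)
  slice <- ct_slice(matrix(0L, 8, 8), 1)
  expect_error(read_compartment_map(p2, slice), "shape")
})

test_that("results CSV keeps the two-decimal formatting contract", {
  ph <- generate_l3_phantom(small_phantom_spec(seed = 3))
  labels <- segment_tissues(ph$slice, ph$compartments)
  res <- compute_areas(labels, ph$slice, waist_cm = 94.2478)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 1)
  expect_true(all(c("sat_cm2", "tat_cm2", "tsm_cm2", "waist_cm") %in%
                    names(back)))
  expect_equal(back$sat_cm2, round(res$areas[["SAT"]], 2))
  expect_equal(back$waist_cm, 94.25)
  expect_error(write_results(list(), withr::local_tempfile()), "empty")
})

test_that("manifest validation enforces dates and required columns", {
  dir <- withr::local_tempdir()
  m <- data.frame(patient_id = "A", pre_path = "a.dcm", pre_map = "a.png",
                  post_path = "b.dcm", post_map = "b.png",
                  pre_date = "2020-03-01", surgery_date = "2020-01-15",
                  post_date = "2020-06-01")
  p <- file.path(dir, "m.csv")
  write_manifest(m, p)
  expect_error(read_manifest(p), "pre_date <= surgery_date")
  m$pre_date <- "2020-01-01"
  write_manifest(m, p)
  mm <- read_manifest(p)
  expect_equal(mm$interval_days, as.integer(as.Date("2020-06-01") -
                                              as.Date("2020-01-01")))
  write_manifest(m[, -1], p)
  expect_error(read_manifest(p), "patient_id")
})
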