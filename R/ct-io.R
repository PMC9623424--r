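#' Read and write label rasters as 8-bit PNG
#'
#' Compartment maps and ground-truth tissue rasters travel as grayscale
#' 8-bit PNGs whose pixel value is the integer label code (0--255). For
#' compartment maps the palette is the one in [COMPARTMENTS]
#' (0 background, 1 subcutaneous, 2 muscular, 3 visceral, 4 bone); for
#' phantom tissue rasters it is the index of [PHANTOM_TISSUES] minus one.
#'
#' @param path PNG file path.
#' @param slice optional [ct_slice()] the map must match in shape.
#' @return `read_compartment_map` returns a [compartment_map()];
#'   `read_tissue_raster` an integer matrix of phantom tissue codes.
#' @export
read_compartment_map <- function(path, slice = NULL) {
  labels <- read_label_png(path)
  bad <- setdiff(unique(as.vector(labels)), unname(COMPARTMENTS))
  if (length(bad))
    stopf("compartment raster %s contains unassigned code(s): %s",
          path, paste(sort(bad), collapse = ", "))
  compartment_map(labels, slice)
}

#' @param map a [compartment_map()] to serialize.
#' @rdname read_compartment_map
#' @export
write_compartment_map <- function(map, path) {
  stopifnot(inherits(map, "compartment_map"))
  write_label_png(map$labels, path)
}

#' @rdname read_compartment_map
#' @export
read_tissue_raster <- function(path, slice = NULL) {
  labels <- read_label_png(path)
  bad <- setdiff(unique(as.vector(labels)), unname(PHANTOM_TISSUE_CODES))
  if (length(bad))
    stopf("tissue raster %s contains unassigned code(s): %s",
          path, paste(sort(bad), collapse = ", "))
  if (!is.null(slice) && !identical(dim(labels), dim(slice$pixels)))
    stopf("tissue raster shape (%s) does not match slice shape (%s)",
          paste(dim(labels), collapse = "x"),
          paste(dim(slice$pixels), collapse = "x"))
  labels
}

write_label_png <- function(labels, path) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 255L))
    stopf("label codes must fit 8-bit PNG (0-255)")
  png::writePNG(labels / 255, target = path)
  invisible(path)
}

read_label_png <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]   # tolerate gray-alpha
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Write per-scan body-composition results as CSV
#'
#' One row per scan with the eight tissue areas, the total-adipose (TAT) and
#' total-skeletal-muscle (TSM) sums, and waist circumference. Units are
#' embedded in the header (`*_cm2`, `*_cm`); numeric values are written at
#' fixed two-decimal precision, mirroring how such tables are reported.
#'
#' @param results a list of [body_composition_result()] objects, or a data
#'   frame already in row form (from [as.data.frame.body_composition_result()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "body_composition_result")) results <- list(results)
  if (is.data.frame(results)) df <- results
  else {
    if (length(results) == 0L)
      stopf("no results to write: refusing to create an empty file")
    df <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (nrow(df) == 0L)
    stopf("no results to write: refusing to create an empty file")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write paired-cohort manifests
#'
#' A manifest is a CSV with one row per patient:
#' `patient_id, pre_path, pre_map, post_path, post_map, pre_date,
#' surgery_date, post_date`. Paths point to single-slice DICOM files and
#' their compartment-map PNGs; dates are ISO-8601 (`YYYY-MM-DD`) and must
#' satisfy `pre_date <= surgery_date <= post_date`.
#'
#' @param path manifest CSV path.
#' @param manifest a data frame with the columns above.
#' @return `read_manifest` returns the manifest with `Date` columns and an
#'   `interval_days` column (`post_date - pre_date`).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pre_path", "pre_map", "post_path", "post_map",
            "pre_date", "surgery_date", "post_date")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stopf("manifest %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  for (col in c("pre_date", "surgery_date", "post_date"))
    m[[col]] <- as.Date(m[[col]])
  bad <- which(m$pre_date > m$surgery_date | m$surgery_date > m$post_date)
  if (length(bad))
    stopf("manifest rows violate pre_date <= surgery_date <= post_date: %s",
          paste(m$patient_id[bad], collapse = ", "))
  m$interval_days <- as.integer(m$post_date - m$pre_date)
  if (any(m$interval_days < 1L))
    stopf("inter-scan interval below 1 day for: %s",
          paste(m$patient_id[m$interval_days < 1L], collapse = ", "))
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
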