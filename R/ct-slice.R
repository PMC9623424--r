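#' CT slice and compartment map containers
#'
#' A `ct_slice` holds a single axial CT image as an integer matrix of
#' Hounsfield units (rows x columns, row-major anatomy as stored in the
#' image) together with its physical pixel spacing in mm. A
#' `compartment_map` is the spatial prior paired with a slice: an integer
#' matrix over the codes in [COMPARTMENTS] (background, subcutaneous,
#' muscular, visceral, bone) of identical shape. The compartment map stands
#' in for the radiologist-guided delineation of fat depots: SAT, IMAT and VAT
#' share overlapping HU ranges and are told apart only by compartment.
#'
#' @param pixels integer matrix of HU values; values outside
#'   \eqn{[-1024, 3071]} (the 12-bit CT convention) are clamped with a
#'   message.
#' @param pixel_spacing numeric length-2, mm per pixel along (row, column).
#' @param patient_id opaque identifier string.
#' @param acquisition_date `Date` or `NA`.
#' @return an object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, pixel_spacing, patient_id = NA_character_,
                     acquisition_date = as.Date(NA)) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stopf("pixel_spacing must be two positive values (mm/pixel)")
  n_clamped <- sum(pixels < -1024 | pixels > 3071, na.rm = TRUE)
  if (n_clamped > 0) {
    message(sprintf("clamped %d pixel(s) to the HU range [-1024, 3071]",
                    n_clamped))
    pixels <- clamp(pixels, -1024, 3071)
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         pixel_spacing = as.numeric(pixel_spacing),
         patient_id = as.character(patient_id),
         acquisition_date = as.Date(acquisition_date)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, %.3g x %.3g mm/px, patient %s\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$patient_id))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$pixels)

# Physical pixel area in mm^2 (supports non-square pixels).
pixel_area_mm2 <- function(slice) prod(slice$pixel_spacing)

#' @param labels integer matrix over the codes in [COMPARTMENTS].
#' @param slice the `ct_slice` the map belongs to (shape check).
#' @rdname ct_slice
#' @export
compartment_map <- function(labels, slice = NULL) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(COMPARTMENTS))
  if (length(bad))
    stopf("unknown compartment code(s): %s", paste(sort(bad), collapse = ", "))
  if (!is.null(slice) && !identical(dim(labels), dim(slice$pixels)))
    stopf("compartment map shape (%s) does not match slice shape (%s)",
          paste(dim(labels), collapse = "x"),
          paste(dim(slice$pixels), collapse = "x"))
  structure(list(labels = labels), class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = unname(COMPARTMENTS),
                      labels = names(COMPARTMENTS)))
  cat(sprintf("<compartment_map> %d x %d px\n", nrow(x$labels), ncol(x$labels)))
  print(tab)
  invisible(x)
}
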