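#' Segment an L3 slice into tissue classes
#'
#' Classifies every pixel by the conjunction of two conditions: its HU value
#' falls in a class's closed interval AND its compartment admits that class.
#' A pixel meeting neither (bone, background air, visceral parenchyma, or
#' visceral fat outside the narrower \eqn{[-150, -50]} visceral window)
#' stays `unclassified`. Within the muscular compartment the scheme's
#' intervals partition \eqn{[-190, 200]} HU, so every muscular-compartment
#' pixel in that range receives exactly one label.
#'
#' @param slice a [ct_slice()].
#' @param compartments a [compartment_map()] of the same shape.
#' @param scheme a threshold scheme; defaults to [default_threshold_scheme()].
#' @return a `tissue_label_map`: integer matrix (0 = unclassified, otherwise
#'   the index of the class in [TISSUE_CLASSES]), with attribute `tissues`.
#' @export
#' @examples
#' ph <- generate_l3_phantom(phantom_spec(image_size = 128,
#'                                        pixel_spacing = 3, seed = 1))
#' labels <- segment_tissues(ph$slice, ph$compartments)
#' table(tissue_of(labels))
segment_tissues <- function(slice, compartments,
                            scheme = default_threshold_scheme()) {
  stopifnot(inherits(slice, "ct_slice"), inherits(compartments, "compartment_map"))
  validate_threshold_scheme(scheme)
  hu <- slice$pixels
  comp <- compartments$labels
  if (!identical(dim(hu), dim(comp)))
    stopf("slice shape (%s) and compartment map shape (%s) differ",
          paste(dim(hu), collapse = "x"), paste(dim(comp), collapse = "x"))

  labels <- matrix(0L, nrow(hu), ncol(hu))
  for (i in seq_len(nrow(scheme))) {
    code <- match(scheme$tissue[i], TISSUE_CLASSES)
    comp_code <- COMPARTMENTS[[scheme$compartment[i]]]
    sel <- comp == comp_code & hu >= scheme$lo[i] & hu <= scheme$hi[i]
    labels[sel] <- code
  }
  structure(labels, class = "tissue_label_map", tissues = TISSUE_CLASSES)
}

#' @param labels a `tissue_label_map`.
#' @rdname segment_tissues
#' @export
tissue_of <- function(labels) {
  factor(as.vector(unclass(labels)), levels = 0:length(TISSUE_CLASSES),
         labels = c("unclassified", TISSUE_CLASSES))
}

#' Per-scan body-composition result
#'
#' Container for one scan's tissue areas (cm^2), their totals and waist
#' circumference. The totals are identities, not measurements: total adipose
#' tissue (TAT) is SAT + IMAT + VAT and total skeletal muscle (TSM) is the
#' sum of the five density classes.
#'
#' @param areas named numeric vector of areas in cm^2 over [TISSUE_CLASSES].
#' @param waist_cm waist circumference in cm (may be `NA`).
#' @param patient_id,scan_date scan identifiers.
#' @return object of class `body_composition_result`.
#' @export
body_composition_result <- function(areas, waist_cm = NA_real_,
                                    patient_id = NA_character_,
                                    scan_date = as.Date(NA)) {
  areas <- areas[TISSUE_CLASSES]
  if (anyNA(areas)) stopf("areas must be named over all of: %s",
                          paste(TISSUE_CLASSES, collapse = ", "))
  if (any(areas < 0)) stopf("negative tissue area")
  structure(
    list(areas = areas,
         tat_cm2 = sum(areas[ADIPOSE_CLASSES]),
         tsm_cm2 = sum(areas[MUSCLE_CLASSES]),
         waist_cm = waist_cm,
         patient_id = as.character(patient_id),
         scan_date = as.Date(scan_date)),
    class = "body_composition_result"
  )
}

#' @export
print.body_composition_result <- function(x, ...) {
  cat(sprintf("<body_composition> patient %s, %s\n", x$patient_id,
              format(x$scan_date)))
  print(round(c(x$areas, TAT = x$tat_cm2, TSM = x$tsm_cm2), 2))
  cat(sprintf("waist: %s cm\n",
              if (is.na(x$waist_cm)) "NA" else sprintf("%.2f", x$waist_cm)))
  invisible(x)
}

#' @export
as.data.frame.body_composition_result <- function(x, ...) {
  df <- data.frame(patient_id = x$patient_id,
                   scan_date = x$scan_date,
                   stringsAsFactors = FALSE)
  for (t in TISSUE_CLASSES) df[[paste0(tolower(t), "_cm2")]] <- x$areas[[t]]
  df$tat_cm2 <- x$tat_cm2
  df$tsm_cm2 <- x$tsm_cm2
  df$waist_cm <- x$waist_cm
  df
}

#' Quantify tissue areas from a label map
#'
#' Area of a class is its pixel count times the physical pixel area
#' (`row_spacing * col_spacing` mm^2), converted to cm^2. Doubling the pixel
#' spacing therefore quadruples every area for the same label map.
#'
#' @param labels a `tissue_label_map` from [segment_tissues()].
#' @param slice the [ct_slice()] the labels came from (provides spacing and
#'   identifiers).
#' @param waist_cm optional waist circumference to carry along.
#' @return a [body_composition_result()].
#' @export
compute_areas <- function(labels, slice, waist_cm = NA_real_) {
  stopifnot(inherits(labels, "tissue_label_map"), inherits(slice, "ct_slice"))
  if (!identical(dim(unclass(labels)), dim(slice$pixels)))
    stopf("label map and slice shapes differ")
  counts <- tabulate(as.vector(unclass(labels)), nbins = length(TISSUE_CLASSES))
  areas <- stats::setNames(counts * pixel_area_mm2(slice) / 100, TISSUE_CLASSES)
  body_composition_result(areas, waist_cm = waist_cm,
                          patient_id = slice$patient_id,
                          scan_date = slice$acquisition_date)
}
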