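#' Tissue classes and anatomical compartments
#'
#' The pipeline distinguishes eight segmentable tissue classes on an L3 CT
#' slice: three adipose depots -- subcutaneous (SAT), intermuscular (IMAT) and
#' visceral (VAT) adipose tissue, the same tissue type separated purely by
#' anatomical compartment -- and five skeletal-muscle density classes, from
#' very low-density (VLDM, myosteatotic) to very high-density muscle (VHDM).
#' Phantom rasters additionally carry AIR, ORGAN (visceral parenchyma) and
#' BONE labels that must never be classified as any of the eight.
#'
#' @format `TISSUE_CLASSES` is a character vector of the eight segmentable
#'   classes; `COMPARTMENTS` the five spatial-prior labels of a compartment
#'   map; `PHANTOM_TISSUES` all eleven ground-truth labels a phantom can emit.
#' @name tissue-classes
NULL

#' @rdname tissue-classes
#' @export
TISSUE_CLASSES <- c("SAT", "IMAT", "VAT", "VLDM", "LDM", "NDM", "HDM", "VHDM")

#' @rdname tissue-classes
#' @export
MUSCLE_CLASSES <- c("VLDM", "LDM", "NDM", "HDM", "VHDM")

#' @rdname tissue-classes
#' @export
ADIPOSE_CLASSES <- c("SAT", "IMAT", "VAT")

#' @rdname tissue-classes
#' @export
COMPARTMENTS <- c(background = 0L, subcutaneous = 1L, muscular = 2L,
                  visceral = 3L, bone = 4L)

#' @rdname tissue-classes
#' @export
PHANTOM_TISSUES <- c("AIR", TISSUE_CLASSES, "ORGAN", "BONE")

# Integer codes used in ground-truth tissue rasters (PNG sidecars).
PHANTOM_TISSUE_CODES <- stats::setNames(seq_along(PHANTOM_TISSUES) - 1L,
                                        PHANTOM_TISSUES)

#' Default Hounsfield-unit emission model for phantom tissues
#'
#' Mean HU per tissue used when rendering synthetic L3 slices. Each
#' segmentable tissue's mean sits at least 10 HU interior to its threshold
#' interval in [default_threshold_scheme()], so Gaussian noise with SD up to
#' about 3 HU essentially never flips a pixel's class; ORGAN (40 HU) falls
#' inside the visceral compartment but outside the visceral-fat window, and
#' BONE (400 HU) is outside every window.
#'
#' @param overrides optional named numeric vector of mean HU values replacing
#'   individual defaults (names from [PHANTOM_TISSUES]).
#' @return named numeric vector of mean HU per phantom tissue.
#' @export
#' @examples
#' default_hu_means()[["SAT"]]
default_hu_means <- function(overrides = NULL) {
  means <- c(AIR = -1000, SAT = -100, IMAT = -80, VAT = -90,
             VLDM = -15, LDM = 20, NDM = 60, HDM = 125, VHDM = 175,
             ORGAN = 40, BONE = 400)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(means))
    if (length(bad)) stopf("unknown tissue(s) in overrides: %s",
                           paste(bad, collapse = ", "))
    means[names(overrides)] <- overrides
  }
  means
}
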