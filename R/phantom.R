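#' Specify a synthetic L3 phantom
#'
#' The phantom emulates the gross geometry of an abdominal cross-section at
#' the third lumbar vertebra as concentric ellipses: an outer body ellipse
#' whose rim (down to the muscle fascia) is subcutaneous fat, a muscular
#' ring containing randomly placed intermuscular-fat disks, a visceral
#' cavity containing visceral-fat disks embedded in organ parenchyma, and a
#' central vertebral-bone disk. Every pixel's true tissue is recorded, so
#' segmentation can be checked pixel-for-pixel. Geometry is deliberately
#' simple -- it exercises every classification rule without claiming
#' anatomical realism.
#'
#' @param image_size square image side in pixels.
#' @param pixel_spacing mm per pixel (scalar, or length 2 for row/column).
#' @param body_axes,fascia_axes,cavity_axes semi-axes in mm of the body,
#'   muscle-fascia and visceral-cavity ellipses, as `c(horizontal,
#'   vertical)`; must be strictly nested.
#' @param vat_fraction,imat_fraction target fraction of the visceral cavity
#'   (resp. muscular ring) occupied by fat disks, in `[0, 1)`.
#' @param muscle_class_mix probability of each muscle density class for a
#'   muscular-ring pixel; must sum to 1. Defaults reflect the approximate
#'   area shares of the five classes in published L3 cohorts (normal-density
#'   muscle dominating).
#' @param vertebra_radius radius in mm of the central bone disk.
#' @param hu_means named mean HU per tissue; see [default_hu_means()].
#' @param noise_sd SD in HU of additive Gaussian noise applied globally.
#' @param blob_radius_mm range of fat-disk radii in mm.
#' @param seed RNG seed; identical spec + seed gives bit-identical phantoms.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512L,
                         pixel_spacing = 1.0,
                         body_axes = c(170, 125),
                         fascia_axes = c(125, 92),
                         cavity_axes = c(100, 70),
                         vat_fraction = 0.25,
                         imat_fraction = 0.05,
                         muscle_class_mix = c(VLDM = 0.146, LDM = 0.278,
                                              NDM = 0.501, HDM = 0.048,
                                              VHDM = 0.027),
                         vertebra_radius = 18,
                         hu_means = default_hu_means(),
                         noise_sd = 2,
                         blob_radius_mm = c(3, 8),
                         seed = 1L) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  spec <- list(image_size = as.integer(image_size),
               pixel_spacing = as.numeric(pixel_spacing),
               body_axes = as.numeric(body_axes),
               fascia_axes = as.numeric(fascia_axes),
               cavity_axes = as.numeric(cavity_axes),
               vat_fraction = vat_fraction, imat_fraction = imat_fraction,
               muscle_class_mix = muscle_class_mix[MUSCLE_CLASSES],
               vertebra_radius = vertebra_radius,
               hu_means = hu_means, noise_sd = noise_sd,
               blob_radius_mm = as.numeric(blob_radius_mm),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!is_count(image_size)) stopf("image_size must be a positive integer")
    if (any(pixel_spacing <= 0)) stopf("pixel_spacing must be positive")
    if (any(c(body_axes, fascia_axes, cavity_axes) <= 0))
      stopf("all ellipse semi-axes must be positive")
    if (!all(body_axes > fascia_axes))
      stopf("body_axes must strictly exceed fascia_axes component-wise")
    if (!all(fascia_axes > cavity_axes))
      stopf("fascia_axes must strictly exceed cavity_axes component-wise")
    if (vertebra_radius <= 0 || vertebra_radius >= min(cavity_axes))
      stopf("vertebra_radius must be positive and fit inside the cavity")
    if (vat_fraction < 0 || vat_fraction >= 1)
      stopf("vat_fraction must be in [0, 1)")
    if (imat_fraction < 0 || imat_fraction >= 1)
      stopf("imat_fraction must be in [0, 1)")
    if (anyNA(muscle_class_mix) ||
        abs(sum(muscle_class_mix) - 1) > 1e-9)
      stopf("muscle_class_mix must cover %s and sum to 1",
            paste(MUSCLE_CLASSES, collapse = ", "))
    if (noise_sd < 0) stopf("noise_sd must be >= 0")
    # Geometry must fit the field of view with a one-pixel air margin.
    half_mm <- image_size / 2 * pixel_spacing - pixel_spacing
    if (body_axes[1] > half_mm[2])
      stopf("body_axes[1] = %g mm does not fit the %d-px field of view",
            body_axes[1], image_size)
    if (body_axes[2] > half_mm[1])
      stopf("body_axes[2] = %g mm does not fit the %d-px field of view",
            body_axes[2], image_size)
    # Segmentable HU means must sit strictly inside their default windows.
    sch <- default_threshold_scheme()
    for (i in seq_len(nrow(sch))) {
      m <- hu_means[[sch$tissue[i]]]
      if (is.null(m) || m <= sch$lo[i] || m >= sch$hi[i])
        stopf("hu_means[%s] = %s is not strictly inside [%d, %d]",
              sch$tissue[i], format(m), sch$lo[i], sch$hi[i])
    }
  })
  invisible(spec)
}

# Membership matrix of an ellipse with semi-axes (a_col, b_row) mm, centered
# on the image center; xr/xc are pixel-center offsets in mm.
ellipse_mask <- function(xr, xc, axes) {
  outer(xr^2 / axes[2]^2, xc^2 / axes[1]^2, "+") <= 1
}

# Grow random fat disks inside `region` until `target` pixels are covered.
place_blobs <- function(region, xr, xc, radius_range, target) {
  blob <- matrix(FALSE, length(xr), length(xc))
  if (target <= 0L) return(blob)
  idx <- which(region)
  n_iter <- 0L
  while (sum(blob) < target && n_iter < 10000L) {
    n_iter <- n_iter + 1L
    center <- idx[sample.int(length(idx), 1L)]
    r0 <- xr[(center - 1L) %% length(xr) + 1L]
    c0 <- xc[(center - 1L) %/% length(xr) + 1L]
    rad <- stats::runif(1L, radius_range[1], radius_range[2])
    disk <- outer((xr - r0)^2, (xc - c0)^2, "+") <= rad^2
    blob <- blob | (disk & region)
  }
  blob
}

#' Generate a synthetic L3 CT slice with exact ground truth
#'
#' Renders the phantom described by `spec`: assigns every pixel a true
#' tissue, emits HU as the tissue's mean plus Gaussian noise (rounded to
#' integer HU and clamped to \eqn{[-1024, 3071]}), and returns the matching
#' compartment map and ground-truth areas. With `noise_sd = 0` and the
#' default HU means, segmenting the phantom recovers the ground truth
#' pixel-for-pixel.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id,acquisition_date identifiers stamped on the slice.
#' @return a list of class `l3_phantom` with elements `slice` (a
#'   [ct_slice()]), `compartments` (a [compartment_map()]), `tissue_map`
#'   (integer matrix of [PHANTOM_TISSUE_CODES]) and `truth` (list with
#'   `areas`, named cm^2 over [TISSUE_CLASSES], and `waist_cm`, the
#'   analytic body-ellipse perimeter).
#' @export
#' @examples
#' ph <- generate_l3_phantom(phantom_spec(image_size = 128, pixel_spacing = 3,
#'                                        noise_sd = 0, seed = 42))
#' ph$truth$areas
generate_l3_phantom <- function(spec, patient_id = "PHANTOM",
                                acquisition_date = as.Date(NA)) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  xr <- (seq_len(n) - ctr) * spec$pixel_spacing[1]   # row offsets, mm
  xc <- (seq_len(n) - ctr) * spec$pixel_spacing[2]   # column offsets, mm

  in_body   <- ellipse_mask(xr, xc, spec$body_axes)
  in_fascia <- ellipse_mask(xr, xc, spec$fascia_axes)
  in_cavity <- ellipse_mask(xr, xc, spec$cavity_axes)
  in_bone   <- ellipse_mask(xr, xc, rep(spec$vertebra_radius, 2L))

  ring     <- in_fascia & !in_cavity
  visceral <- in_cavity & !in_bone

  tissue <- matrix(PHANTOM_TISSUE_CODES[["AIR"]], n, n)
  tissue[in_body & !in_fascia] <- PHANTOM_TISSUE_CODES[["SAT"]]
  tissue[in_bone] <- PHANTOM_TISSUE_CODES[["BONE"]]

  with_seed(spec$seed, {
    imat <- place_blobs(ring, xr, xc, spec$blob_radius_mm,
                        round(spec$imat_fraction * sum(ring)))
    tissue[imat] <- PHANTOM_TISSUE_CODES[["IMAT"]]
    muscle_px <- which(ring & !imat)
    tissue[muscle_px] <- PHANTOM_TISSUE_CODES[
      sample(MUSCLE_CLASSES, length(muscle_px), replace = TRUE,
             prob = spec$muscle_class_mix)]

    vat <- place_blobs(visceral, xr, xc, spec$blob_radius_mm,
                       round(spec$vat_fraction * sum(visceral)))
    tissue[vat] <- PHANTOM_TISSUE_CODES[["VAT"]]
    tissue[visceral & !vat] <- PHANTOM_TISSUE_CODES[["ORGAN"]]

    mu <- spec$hu_means[PHANTOM_TISSUES][tissue + 1L]
    hu <- if (spec$noise_sd > 0)
      round(mu + stats::rnorm(length(mu), 0, spec$noise_sd)) else round(mu)
  })
  hu <- matrix(clamp(hu, -1024, 3071), n, n)

  comp <- matrix(COMPARTMENTS[["background"]], n, n)
  comp[in_body & !in_fascia] <- COMPARTMENTS[["subcutaneous"]]
  comp[ring] <- COMPARTMENTS[["muscular"]]
  comp[visceral] <- COMPARTMENTS[["visceral"]]
  comp[in_bone] <- COMPARTMENTS[["bone"]]

  slice <- ct_slice(hu, spec$pixel_spacing, patient_id = patient_id,
                    acquisition_date = acquisition_date)
  counts <- vapply(TISSUE_CLASSES,
                   function(t) sum(tissue == PHANTOM_TISSUE_CODES[[t]]),
                   numeric(1))
  truth <- list(
    areas = counts * pixel_area_mm2(slice) / 100,
    waist_cm = ellipse_perimeter(spec$body_axes[1], spec$body_axes[2]) / 10
  )
  structure(list(slice = slice,
                 compartments = compartment_map(comp, slice),
                 tissue_map = tissue,
                 truth = truth,
                 spec = spec),
            class = "l3_phantom")
}

#' @export
print.l3_phantom <- function(x, ...) {
  cat(sprintf("<l3_phantom> %d x %d px, noise SD %g HU, seed %d\n",
              nrow(x$slice$pixels), ncol(x$slice$pixels),
              x$spec$noise_sd, x$spec$seed))
  print(round(x$truth$areas, 2))
  cat(sprintf("true waist: %.2f cm\n", x$truth$waist_cm))
  invisible(x)
}

#' Write a phantom to disk as DICOM + sidecars
#'
#' Emits `<stem>.dcm` (the HU raster as single-frame DICOM),
#' `<stem>_compartments.png` (the spatial prior, [COMPARTMENTS] palette),
#' `<stem>_tissues.png` (ground-truth tissue raster, [PHANTOM_TISSUES]
#' palette) and `<stem>_truth.json` (ground-truth areas and waist).
#'
#' @param phantom an `l3_phantom`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the four paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  stopifnot(inherits(phantom, "l3_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dicom = file.path(dir, paste0(stem, ".dcm")),
    compartments = file.path(dir, paste0(stem, "_compartments.png")),
    tissues = file.path(dir, paste0(stem, "_tissues.png")),
    truth = file.path(dir, paste0(stem, "_truth.json"))
  )
  write_ct_slice(phantom$slice, paths[["dicom"]])
  write_compartment_map(phantom$compartments, paths[["compartments"]])
  write_label_png(phantom$tissue_map, paths[["tissues"]])
  jsonlite::write_json(list(areas_cm2 = as.list(phantom$truth$areas),
                            waist_cm = phantom$truth$waist_cm),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
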