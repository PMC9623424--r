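#' Specify a paired pre/post cohort with known variance components
#'
#' The simulator realizes exactly the two variance components that define
#' test-retest reliability: each patient has a true tissue area
#' \eqn{T_i \sim N(\mu, \sigma_b^2)} (between-patient), and each scan
#' observes it with independent error \eqn{N(0, \sigma_w^2)}
#' (within-patient), with an optional additive systematic post-minus-pre
#' shift. The intraclass correlation is then known by construction:
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param n_patients number of pre/post pairs (>= 3).
#' @param mean_areas named population mean area in cm^2 per tissue; defaults
#'   are presurgery means typical of an opportunistic-CT breast-cancer
#'   cohort at L3.
#' @param sigma_between SD in cm^2 of patient-level true areas.
#' @param sigma_within SD in cm^2 of a single scan's deviation from the
#'   patient's true area.
#' @param systematic_shift additive post - pre effect in cm^2.
#' @param interval_days_distribution `c(mean, sd)` in days of the
#'   pre-to-post inter-scan interval; defaults mirror a published cohort
#'   (590.6 and 536.8 days). Draws are floored at 1 day.
#' @param seed RNG seed.
#' @return a validated `paired_cohort_spec` list.
#' @export
paired_cohort_spec <- function(n_patients = 50L,
                               mean_areas = c(SAT = 308.58, IMAT = 21.51,
                                              VAT = 118.20, VLDM = 18.30,
                                              LDM = 34.89, NDM = 62.85,
                                              HDM = 6.01, VHDM = 3.34),
                               sigma_between = 30,
                               sigma_within = 10,
                               systematic_shift = 0,
                               interval_days_distribution = c(mean = 590.6,
                                                              sd = 536.8),
                               seed = 1L) {
  if (!is_count(n_patients) || n_patients < 3)
    stopf("n_patients must be an integer >= 3")
  if (sigma_between < 0 || sigma_within < 0)
    stopf("variance-component SDs must be >= 0")
  if (is.null(names(mean_areas)) || any(!nzchar(names(mean_areas))))
    stopf("mean_areas must be a named vector")
  if (length(interval_days_distribution) != 2L ||
      any(interval_days_distribution < 0))
    stopf("interval_days_distribution must be c(mean, sd), both >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 mean_areas = mean_areas,
                 sigma_between = sigma_between,
                 sigma_within = sigma_within,
                 systematic_shift = systematic_shift,
                 interval_days_distribution = unname(interval_days_distribution),
                 seed = as.integer(seed)),
            class = "paired_cohort_spec")
}

#' Theoretical intraclass correlation of a simulated cohort
#'
#' The reliability the cohort is built to have: the between-patient variance
#' divided by the sum of the between- and within-patient variances.
#'
#' @param cspec a [paired_cohort_spec()].
#' @return a value in `[0, 1]`.
#' @export
#' @examples
#' theoretical_icc(paired_cohort_spec(sigma_between = 30, sigma_within = 10))
theoretical_icc <- function(cspec) {
  sb2 <- cspec$sigma_between^2
  sw2 <- cspec$sigma_within^2
  if (sb2 + sw2 == 0)
    stopf("both variance components are zero: ICC is undefined")
  sb2 / (sb2 + sw2)
}

#' Simulate a paired pre/post cohort at the area level
#'
#' Draws, per patient and tissue, a true area and two noisy observations of
#' it (see [paired_cohort_spec()]); negative draws are truncated at zero
#' with a warning giving the count. Inter-scan intervals are drawn from the
#' stated normal distribution (floored at 1 day) and split around a surgery
#' date, yielding consistent `pre_date <= surgery_date <= post_date`.
#'
#' @param cspec a [paired_cohort_spec()].
#' @return a long data frame of class `paired_cohort` with columns
#'   `patient_id`, `measure`, `true_area`, `pre`, `post`, plus per-patient
#'   date columns (`pre_date`, `surgery_date`, `post_date`, `interval_days`)
#'   repeated across measures. Deterministic for a fixed spec + seed.
#' @export
generate_paired_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "paired_cohort_spec"))
  n <- cspec$n_patients
  measures <- names(cspec$mean_areas)
  with_seed(cspec$seed, {
    ids <- sprintf("P%03d", seq_len(n))
    interval <- pmax(1L, round(stats::rnorm(
      n, cspec$interval_days_distribution[1],
      cspec$interval_days_distribution[2])))
    surgery <- as.Date("2016-06-01") + sample.int(1200L, n, replace = TRUE)
    gap_pre <- round(interval * stats::runif(n, 0.2, 0.8))
    gap_pre <- pmin(pmax(gap_pre, 0L), interval)

    rows <- vector("list", length(measures))
    n_truncated <- 0L
    for (j in seq_along(measures)) {
      truth <- stats::rnorm(n, cspec$mean_areas[[j]], cspec$sigma_between)
      pre <- truth + stats::rnorm(n, 0, cspec$sigma_within)
      post <- truth + cspec$systematic_shift +
        stats::rnorm(n, 0, cspec$sigma_within)
      n_truncated <- n_truncated + sum(pre < 0) + sum(post < 0) + sum(truth < 0)
      rows[[j]] <- data.frame(patient_id = ids,
                              measure = measures[j],
                              true_area = pmax(truth, 0),
                              pre = pmax(pre, 0),
                              post = pmax(post, 0),
                              stringsAsFactors = FALSE)
    }
  })
  if (n_truncated > 0)
    warnf("truncated %d negative simulated area(s) at 0", n_truncated)
  out <- do.call(rbind, rows)
  ix <- match(out$patient_id, ids)
  out$pre_date <- (surgery - gap_pre)[ix]
  out$surgery_date <- surgery[ix]
  out$post_date <- (surgery + (interval - gap_pre))[ix]
  out$interval_days <- as.integer(interval)[ix]
  class(out) <- c("paired_cohort", "data.frame")
  out
}

#' Render an area-level cohort as DICOM phantoms with a manifest
#'
#' End-to-end mode: each simulated scan is rendered as an L3 phantom whose
#' compartment geometry is scaled so the rendered ground-truth areas match
#' that scan's simulated areas (exactly for blob- and class-allocated
#' tissues, up to ellipse discretization for the subcutaneous ring). Writes
#' per-scan DICOM + compartment PNG pairs and a cohort manifest CSV.
#'
#' @param cspec a [paired_cohort_spec()] whose `mean_areas` cover all of
#'   [TISSUE_CLASSES].
#' @param dir output directory.
#' @param image_size,pixel_spacing,noise_sd rendering parameters passed to
#'   the phantom; the default 256 px at 2 mm keeps a full cohort fast while
#'   holding discretization error well under 1% for compartments of a few
#'   cm^2 and above.
#' @return path of the written manifest CSV; the simulated cohort table is
#'   attached as attribute `cohort`.
#' @export
write_phantom_cohort <- function(cspec, dir, image_size = 256L,
                                 pixel_spacing = 2, noise_sd = 2) {
  stopifnot(inherits(cspec, "paired_cohort_spec"))
  if (!all(TISSUE_CLASSES %in% names(cspec$mean_areas)))
    stopf("image-level rendering needs mean_areas for all of: %s",
          paste(TISSUE_CLASSES, collapse = ", "))
  cohort <- suppressWarnings(generate_paired_cohort(cspec))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ids <- unique(cohort$patient_id)
  scan_seed <- (cspec$seed %% 1000000L) * 1000L   # derived seeds < 2^31
  manifest <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- cohort[cohort$patient_id == ids[i], ]
    targets_pre <- stats::setNames(rows$pre, rows$measure)[TISSUE_CLASSES]
    targets_post <- stats::setNames(rows$post, rows$measure)[TISSUE_CLASSES]
    stem_pre <- sprintf("%s_pre", ids[i])
    stem_post <- sprintf("%s_post", ids[i])
    render_scan_to_targets(targets_pre, dir, stem_pre, ids[i],
                           rows$pre_date[1], image_size, pixel_spacing,
                           noise_sd, seed = scan_seed + 2L * i)
    render_scan_to_targets(targets_post, dir, stem_post, ids[i],
                           rows$post_date[1], image_size, pixel_spacing,
                           noise_sd, seed = scan_seed + 2L * i + 1L)
    manifest[[i]] <- data.frame(
      patient_id = ids[i],
      pre_path = file.path(dir, paste0(stem_pre, ".dcm")),
      pre_map = file.path(dir, paste0(stem_pre, "_compartments.png")),
      post_path = file.path(dir, paste0(stem_post, ".dcm")),
      post_map = file.path(dir, paste0(stem_post, "_compartments.png")),
      pre_date = rows$pre_date[1],
      surgery_date = rows$surgery_date[1],
      post_date = rows$post_date[1],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, path)
  attr(path, "cohort") <- cohort
  path
}

# Render one scan whose ground-truth areas hit the per-tissue targets (cm^2):
# fascia and body ellipses are scaled so ring/rim areas match, and blob/class
# pixels are allocated by exact count within their compartments.
render_scan_to_targets <- function(targets, dir, stem, patient_id, scan_date,
                                   image_size, pixel_spacing, noise_sd, seed) {
  px_mm2 <- pixel_spacing^2
  cavity <- c(100, 70)
  vert_r <- 18
  ring_mm2 <- sum(targets[c("IMAT", MUSCLE_CLASSES)]) * 100
  ff <- prod(cavity) + ring_mm2 / pi          # required fascia axes product
  fascia <- c(125, 92) * sqrt(ff / prod(c(125, 92)))
  sat_mm2 <- targets[["SAT"]] * 100
  bb <- prod(fascia) + sat_mm2 / pi
  body <- c(170, 125) * sqrt(bb / prod(c(170, 125)))
  half_mm <- image_size / 2 * pixel_spacing - pixel_spacing
  if (max(body) > half_mm)
    stopf("simulated areas for %s need a body semi-axis of %.0f mm, beyond the %d-px field of view",
          patient_id, max(body), image_size)

  n <- image_size
  ctr <- (n + 1) / 2
  xr <- (seq_len(n) - ctr) * pixel_spacing
  xc <- xr
  in_body   <- ellipse_mask(xr, xc, body)
  in_fascia <- ellipse_mask(xr, xc, fascia)
  in_cavity <- ellipse_mask(xr, xc, cavity)
  in_bone   <- ellipse_mask(xr, xc, rep(vert_r, 2L))
  ring      <- in_fascia & !in_cavity
  visceral  <- in_cavity & !in_bone

  tissue <- matrix(PHANTOM_TISSUE_CODES[["AIR"]], n, n)
  tissue[in_body & !in_fascia] <- PHANTOM_TISSUE_CODES[["SAT"]]
  tissue[in_bone] <- PHANTOM_TISSUE_CODES[["BONE"]]

  with_seed(seed, {
    # Exact pixel counts per ring class; the largest class absorbs rounding.
    ring_px <- which(ring)
    counts <- round(targets[c("IMAT", MUSCLE_CLASSES)] * 100 / px_mm2)
    counts <- pmin(counts, length(ring_px))
    biggest <- names(which.max(counts))
    counts[biggest] <- counts[biggest] + (length(ring_px) - sum(counts))
    if (counts[biggest] < 0) counts[biggest] <- 0
    alloc <- sample(ring_px)
    offset <- 0L
    for (cls in names(counts)) {
      take <- alloc[offset + seq_len(counts[[cls]])]
      tissue[take] <- PHANTOM_TISSUE_CODES[[cls]]
      offset <- offset + counts[[cls]]
    }
    # Visceral cavity: exact VAT count, rest organ parenchyma.
    visc_px <- which(visceral)
    n_vat <- min(round(targets[["VAT"]] * 100 / px_mm2), length(visc_px))
    alloc <- sample(visc_px)
    tissue[alloc[seq_len(n_vat)]] <- PHANTOM_TISSUE_CODES[["VAT"]]
    tissue[alloc[-seq_len(n_vat)]] <- PHANTOM_TISSUE_CODES[["ORGAN"]]

    mu <- default_hu_means()[PHANTOM_TISSUES][tissue + 1L]
    hu <- if (noise_sd > 0) round(mu + stats::rnorm(length(mu), 0, noise_sd))
          else round(mu)
  })
  hu <- matrix(clamp(hu, -1024, 3071), n, n)

  comp <- matrix(COMPARTMENTS[["background"]], n, n)
  comp[in_body & !in_fascia] <- COMPARTMENTS[["subcutaneous"]]
  comp[ring] <- COMPARTMENTS[["muscular"]]
  comp[visceral] <- COMPARTMENTS[["visceral"]]
  comp[in_bone] <- COMPARTMENTS[["bone"]]

  slice <- ct_slice(hu, pixel_spacing, patient_id = patient_id,
                    acquisition_date = scan_date)
  write_ct_slice(slice, file.path(dir, paste0(stem, ".dcm")))
  write_compartment_map(compartment_map(comp, slice),
                        file.path(dir, paste0(stem, "_compartments.png")))
  invisible(NULL)
}
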