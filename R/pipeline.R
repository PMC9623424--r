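#' Pipeline configuration
#'
#' @param scheme a threshold scheme or a YAML path understood by
#'   [read_threshold_scheme()]; `NULL` means [default_threshold_scheme()].
#' @param cutoff_years interval cutoff separating the reliability strata
#'   (default 3: scans three or fewer years apart vs farther apart).
#' @param alpha two-sided significance level for ICC confidence intervals.
#' @param out_dir directory for report CSVs, or `NULL` to skip writing.
#' @param seed echoed into the report for simulation-backed runs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scheme = NULL, cutoff_years = 3, alpha = 0.05,
                            out_dir = NULL, seed = NA_integer_) {
  if (cutoff_years <= 0) stopf("cutoff_years must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (is.character(scheme)) scheme <- read_threshold_scheme(scheme)
  if (is.null(scheme)) scheme <- default_threshold_scheme()
  validate_threshold_scheme(scheme)
  structure(list(scheme = scheme, cutoff_years = cutoff_years, alpha = alpha,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Stratify paired records by inter-scan interval
#'
#' Splits records at `cutoff_years`, converted at 365.25 days/year with the
#' boundary inclusive on the within side ("three or fewer years apart"), and
#' preserves the input order within each stratum.
#'
#' @param records data frame with an `interval_days` column.
#' @param cutoff_years cutoff in years.
#' @return list with elements `within` and `beyond`.
#' @export
#' @examples
#' r <- data.frame(patient_id = 1:2, interval_days = c(1095, 1096))
#' sapply(stratify_by_interval(r, 3), nrow)
stratify_by_interval <- function(records, cutoff_years = 3) {
  if (!"interval_days" %in% names(records))
    stopf("records need an interval_days column")
  cutoff_days <- cutoff_years * 365.25
  within <- records$interval_days <= cutoff_days
  list(within = records[within, , drop = FALSE],
       beyond = records[!within, , drop = FALSE])
}

#' Summarize scan-date intervals
#'
#' Three rows of calendar-day intervals -- pre-to-post, pre-to-surgery and
#' surgery-to-post -- each summarized by [interval_summary()]. Differences
#' are exact calendar-day counts (leap days included).
#'
#' @param records data frame with one row per patient and `Date` columns
#'   `pre_date`, `surgery_date`, `post_date`.
#' @return data frame with columns `interval`, `mean`, `sd`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
summarize_intervals <- function(records) {
  if (nrow(records) == 0) stopf("no records to summarize")
  spans <- list(
    pre_to_post = as.numeric(records$post_date - records$pre_date),
    pre_to_surgery = as.numeric(records$surgery_date - records$pre_date),
    surgery_to_post = as.numeric(records$post_date - records$surgery_date)
  )
  out <- do.call(rbind, lapply(spans, function(v)
    as.data.frame(as.list(suppressWarnings(interval_summary(v))))))
  cbind(data.frame(interval = names(spans), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

icc_row <- function(measure, pre, post, alpha, stratum = NA_character_) {
  base <- data.frame(measure = measure, stratum = stratum, n = length(pre),
                     icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     ms_between = NA_real_, ms_error = NA_real_,
                     stringsAsFactors = FALSE)
  est <- tryCatch(icc_3_1(pre, post, alpha = alpha), error = function(e) NULL)
  if (!is.null(est)) {
    base$icc <- est$icc; base$ci_low <- est$ci_low; base$ci_high <- est$ci_high
    base$ms_between <- est$ms_between; base$ms_error <- est$ms_error
  }
  base
}

#' Reliability analysis of a paired long table
#'
#' The statistical core of [run_cohort()], usable directly on area-level
#' simulated cohorts: per measure, a paired change summary (Wilcoxon
#' signed-rank p on the differences, percent change on the group means), the
#' overall ICC(3,1) with confidence interval, and ICCs stratified by
#' inter-scan interval. Waist circumference, when present, appears in the
#' change table but not the ICC tables. Strata too small for an ICC
#' (fewer than 3 pairs, or no variance) yield `NA` rows rather than errors;
#' negative ICCs and very wide intervals are reported exactly as computed.
#'
#' @param paired long data frame with columns `patient_id`, `measure`,
#'   `pre`, `post`, `interval_days`, optionally the three date columns.
#' @param config a [pipeline_config()].
#' @return a `reliability_report` list with `change_table`, `icc_overall`,
#'   `icc_stratified`, `interval_table` (when dates are present),
#'   `stratum_sizes` and `config`.
#' @export
analyze_paired_cohort <- function(paired, config = pipeline_config()) {
  need <- c("patient_id", "measure", "pre", "post", "interval_days")
  missing <- setdiff(need, names(paired))
  if (length(missing))
    stopf("paired table lacks column(s): %s", paste(missing, collapse = ", "))
  n_pairs <- length(unique(paired$patient_id))
  if (n_pairs < 3) stopf("need at least 3 complete pairs (got %d)", n_pairs)

  order_hint <- c(TISSUE_CLASSES, "TAT", "TSM", "WAIST")
  measures <- unique(paired$measure)
  measures <- c(intersect(order_hint, measures), setdiff(measures, order_hint))
  icc_measures <- setdiff(measures, "WAIST")

  change <- do.call(rbind, lapply(measures, function(m) {
    sub <- paired[paired$measure == m, ]
    cbind(data.frame(measure = m, stringsAsFactors = FALSE),
          suppressMessages(change_summary(sub$pre, sub$post)))
  }))

  overall <- do.call(rbind, lapply(icc_measures, function(m) {
    sub <- paired[paired$measure == m, ]
    icc_row(m, sub$pre, sub$post, config$alpha, stratum = "overall")
  }))

  strata <- stratify_by_interval(paired, config$cutoff_years)
  stratified <- do.call(rbind, lapply(names(strata), function(s) {
    sub_all <- strata[[s]]
    do.call(rbind, lapply(icc_measures, function(m) {
      sub <- sub_all[sub_all$measure == m, ]
      icc_row(m, sub$pre, sub$post, config$alpha, stratum = s)
    }))
  }))

  patients <- paired[!duplicated(paired$patient_id), , drop = FALSE]
  pstrata <- stratify_by_interval(patients, config$cutoff_years)
  stratum_sizes <- c(within = nrow(pstrata$within), beyond = nrow(pstrata$beyond))

  interval_table <- if (all(c("pre_date", "surgery_date", "post_date") %in%
                            names(paired)))
    summarize_intervals(patients) else NULL

  report <- structure(list(change_table = change,
                           icc_overall = overall,
                           icc_stratified = stratified,
                           interval_table = interval_table,
                           stratum_sizes = stratum_sizes,
                           n_pairs = n_pairs,
                           config = config,
                           skipped = NULL),
                      class = "reliability_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Run the full pipeline over a cohort manifest
#'
#' For every manifest row: read the pre and post DICOM slices and their
#' compartment maps, segment with the configured threshold scheme, quantify
#' the eight tissue areas plus TAT, TSM and waist circumference, then hand
#' the paired table to [analyze_paired_cohort()]. Scans that cannot be read
#' or segmented cause the record to be skipped with a logged reason (listed
#' in the report); fewer than 3 surviving pairs is a hard error. The run is
#' fully deterministic given the input files.
#'
#' @param manifest path to a manifest CSV (see [read_manifest()]).
#' @param config a [pipeline_config()].
#' @return a `reliability_report`; also written as CSVs + `report.md` when
#'   `config$out_dir` is set. The per-scan results table is attached as
#'   `$scan_results`.
#' @export
run_cohort <- function(manifest, config = pipeline_config()) {
  m <- read_manifest(manifest)
  rows <- list()
  scans <- list()
  skipped <- list()
  for (i in seq_len(nrow(m))) {
    rec <- m[i, ]
    res <- tryCatch({
      pre <- measure_scan(rec$pre_path, rec$pre_map, config$scheme)
      post <- measure_scan(rec$post_path, rec$post_map, config$scheme)
      list(pre = pre, post = post)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(patient_id = rec$patient_id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    vals_pre <- c(res$pre$areas, TAT = res$pre$tat_cm2, TSM = res$pre$tsm_cm2,
                  WAIST = res$pre$waist_cm)
    vals_post <- c(res$post$areas, TAT = res$post$tat_cm2,
                   TSM = res$post$tsm_cm2, WAIST = res$post$waist_cm)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rec$patient_id,
      measure = names(vals_pre),
      pre = unname(vals_pre), post = unname(vals_post),
      pre_date = rec$pre_date, surgery_date = rec$surgery_date,
      post_date = rec$post_date, interval_days = rec$interval_days,
      stringsAsFactors = FALSE)
    df_pre <- as.data.frame(res$pre); df_pre$scan <- "pre"
    df_post <- as.data.frame(res$post); df_post$scan <- "post"
    scans[[length(scans) + 1L]] <- rbind(df_pre, df_post)
  }
  if (length(rows) < 3)
    stopf("only %d complete pair(s) survived reading/segmentation (need >= 3)",
          length(rows))
  paired <- do.call(rbind, rows)
  core_config <- config
  core_config$out_dir <- NULL
  report <- analyze_paired_cohort(paired, core_config)
  report$config <- config
  report$skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  report$scan_results <- do.call(rbind, scans)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Segment one scan and return its body_composition_result (with waist).
measure_scan <- function(dicom_path, map_path, scheme) {
  slice <- read_ct_slice(dicom_path)
  comp <- read_compartment_map(map_path, slice)
  labels <- segment_tissues(slice, comp, scheme)
  waist <- measure_waist_circumference(slice)
  compute_areas(labels, slice, waist_cm = waist)
}

format_p <- function(p) {
  ifelse(is.na(p), "no change",
         ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
}

#' Write a reliability report to disk
#'
#' Emits `intervals.csv`, `change.csv`, `icc_overall.csv`,
#' `icc_stratified.csv` (full precision) and a human-readable `report.md`
#' (p-values to three decimals, floored at `<.001`), plus `run.log` with
#' skipped records and the configuration echo.
#'
#' @param report a `reliability_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$interval_table))
    utils::write.csv(report$interval_table, file.path(dir, "intervals.csv"),
                     row.names = FALSE)
  utils::write.csv(report$change_table, file.path(dir, "change.csv"),
                   row.names = FALSE)
  utils::write.csv(report$icc_overall, file.path(dir, "icc_overall.csv"),
                   row.names = FALSE)
  utils::write.csv(report$icc_stratified, file.path(dir, "icc_stratified.csv"),
                   row.names = FALSE)

  md <- c("# L3 body-composition reliability report", "",
          sprintf("Complete pairs: %d (within %g y: %d; beyond: %d)",
                  report$n_pairs, report$config$cutoff_years,
                  report$stratum_sizes[["within"]],
                  report$stratum_sizes[["beyond"]]), "")
  ct <- report$change_table
  md <- c(md, "## Pre vs post change", "",
          "| measure | pre mean (SD) | post mean (SD) | diff mean (SD) | % change | p |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %.2f (%.2f) | %.2f (%.2f) | %.2f (%.2f) | %.2f | %s |",
                  ct$measure, ct$pre_mean, ct$pre_sd, ct$post_mean, ct$post_sd,
                  ct$diff_mean, ct$diff_sd, ct$percent_change,
                  format_p(ct$wilcoxon_p)), "")
  it <- report$icc_overall
  md <- c(md, "## Intraindividual reliability, ICC(3,1)", "",
          "| measure | n | ICC (95% CI) |", "|---|---|---|",
          sprintf("| %s | %d | %.3f (%.3f to %.3f) |",
                  it$measure, it$n, it$icc, it$ci_low, it$ci_high), "")
  st <- report$icc_stratified
  md <- c(md, "## ICC by inter-scan interval stratum", "",
          "| stratum | measure | n | ICC (95% CI) |", "|---|---|---|---|",
          sprintf("| %s | %s | %d | %.3f (%.3f to %.3f) |",
                  st$stratum, st$measure, st$n, st$icc, st$ci_low, st$ci_high))
  writeLines(md, file.path(dir, "report.md"))

  log <- c(sprintf("cutoff_years: %g", report$config$cutoff_years),
           sprintf("alpha: %g", report$config$alpha),
           sprintf("seed: %s", report$config$seed),
           sprintf("pairs_analyzed: %d", report$n_pairs))
  if (!is.null(report$skipped))
    log <- c(log, sprintf("skipped: %s (%s)", report$skipped$patient_id,
                          report$skipped$reason))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d pairs (%d within %g y, %d beyond)\n",
              x$n_pairs, x$stratum_sizes[["within"]], x$config$cutoff_years,
              x$stratum_sizes[["beyond"]]))
  print(cbind(x$change_table[, c("measure", "pre_mean", "post_mean",
                                 "diff_mean", "percent_change")],
              p = format_p(x$change_table$wilcoxon_p)))
  invisible(x)
}
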