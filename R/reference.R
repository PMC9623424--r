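#' Published reference change table for an L3 body-composition cohort
#'
#' Summary statistics from a published opportunistic-CT cohort of 50
#' breast-cancer patients with paired pre/post-surgery scans: per body
#' composition component, the presurgery and postsurgery mean (SD) areas in
#' cm^2 (waist circumference in cm), the mean (SD) of the post-minus-pre
#' differences, the percent change of the group mean, and the Wilcoxon
#' signed-rank p-value. Useful as a realistic set of defaults and as an
#' arithmetic cross-check: the printed percent-change column reproduces
#' `percent_change(pre_mean, diff_mean)` to two decimals, and the TAT and
#' TSM rows equal the sums of their components.
#'
#' @return data frame with columns `component`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `diff_mean`, `diff_sd`, `percent_change`,
#'   `p_value`. Components are the eight tissue classes plus `TAT`, `TSM`
#'   and `WAIST`.
#' @export
#' @examples
#' ref <- reference_change_table()
#' with(ref[ref$component == "IMAT", ], percent_change(pre_mean, diff_mean))
reference_change_table <- function() {
  path <- system.file("extdata", "reference_cohort_changes.csv",
                      package = "l3bodycomp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
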