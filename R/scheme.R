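#' Hounsfield-unit threshold scheme
#'
#' A threshold scheme maps each tissue class to a closed integer HU interval
#' `[lo, hi]` and the anatomical compartment in which the class is admissible.
#' Because subcutaneous, intermuscular and visceral fat overlap completely in
#' attenuation, the compartment constraint -- not the HU value -- is what
#' separates the three adipose depots.
#'
#' The default scheme uses the published windows: SAT and IMAT share
#' \eqn{[-190, -30]} HU (in the subcutaneous and muscular compartments
#' respectively), VAT is \eqn{[-150, -50]} HU in the visceral compartment, and
#' the five muscle classes partition \eqn{[-29, 200]} HU within the muscular
#' compartment. Published muscle windows touch at their shared endpoints
#' (0, 35, 101, 151 HU); to guarantee a partition on integer HU, each shared
#' boundary is assigned to the lower-density class, giving VLDM
#' \eqn{[-29, 0]}, LDM \eqn{[1, 35]}, NDM \eqn{[36, 101]}, HDM
#' \eqn{[102, 151]} and VHDM \eqn{[152, 200]}.
#'
#' @return a data frame of class `hu_scheme` with columns `tissue`, `lo`,
#'   `hi` (integer HU, closed interval) and `compartment`.
#' @seealso [segment_tissues()], [read_threshold_scheme()]
#' @export
#' @examples
#' default_threshold_scheme()
default_threshold_scheme <- function() {
  scheme <- data.frame(
    tissue      = TISSUE_CLASSES,
    lo          = c(-190L, -190L, -150L, -29L,   1L,  36L, 102L, 152L),
    hi          = c( -30L,  -30L,  -50L,   0L,  35L, 101L, 151L, 200L),
    compartment = c("subcutaneous", "muscular", "visceral",
                    rep("muscular", 5L)),
    stringsAsFactors = FALSE
  )
  class(scheme) <- c("hu_scheme", "data.frame")
  validate_threshold_scheme(scheme)
  scheme
}

#' Validate a threshold scheme
#'
#' Checks structural validity and the muscular-compartment partition
#' invariant: the adipose interval (IMAT) and the five muscle intervals must
#' be pairwise disjoint and jointly cover every integer HU in
#' \eqn{[-190, 200]} exactly once, so that no muscular-compartment pixel in
#' that range is ambiguous or dropped.
#'
#' @param scheme a scheme as returned by [default_threshold_scheme()] or
#'   [read_threshold_scheme()].
#' @return the scheme, invisibly, if valid; otherwise an error.
#' @export
validate_threshold_scheme <- function(scheme) {
  need <- c("tissue", "lo", "hi", "compartment")
  if (!is.data.frame(scheme) || !all(need %in% names(scheme)))
    stopf("threshold scheme must have columns %s", paste(need, collapse = ", "))
  if (!setequal(scheme$tissue, TISSUE_CLASSES))
    stopf("scheme must define exactly the classes: %s",
          paste(TISSUE_CLASSES, collapse = ", "))
  if (any(scheme$lo > scheme$hi))
    stopf("interval with lo > hi for: %s",
          paste(scheme$tissue[scheme$lo > scheme$hi], collapse = ", "))
  bad <- setdiff(scheme$compartment,
                 c("subcutaneous", "muscular", "visceral"))
  if (length(bad)) stopf("unknown compartment(s): %s", paste(bad, collapse = ", "))

  musc <- scheme[scheme$compartment == "muscular", , drop = FALSE]
  covered <- integer(0)
  for (i in seq_len(nrow(musc)))
    covered <- c(covered, seq.int(musc$lo[i], musc$hi[i]))
  full <- seq.int(-190L, 200L)
  if (anyDuplicated(covered))
    stopf("muscular-compartment intervals overlap at HU %s",
          paste(utils::head(unique(covered[duplicated(covered)]), 5L),
                collapse = ", "))
  if (!setequal(covered, full))
    stopf("muscular-compartment intervals do not cover [-190, 200]: missing %d HU values",
          length(setdiff(full, covered)))
  invisible(scheme)
}

#' Read or write a threshold scheme as YAML
#'
#' The on-disk format is a mapping `tissue: {lo: ..., hi: ...,
#' compartment: ...}`, editable by hand to explore alternative windows.
#'
#' @param path YAML file path.
#' @param scheme scheme to serialize.
#' @return `read_threshold_scheme` returns a validated `hu_scheme`;
#'   `write_threshold_scheme` returns `path` invisibly.
#' @export
read_threshold_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  scheme <- data.frame(
    tissue      = names(raw),
    lo          = vapply(raw, function(x) as.integer(x$lo), integer(1)),
    hi          = vapply(raw, function(x) as.integer(x$hi), integer(1)),
    compartment = vapply(raw, function(x) as.character(x$compartment),
                         character(1)),
    stringsAsFactors = FALSE
  )
  rownames(scheme) <- NULL
  class(scheme) <- c("hu_scheme", "data.frame")
  validate_threshold_scheme(scheme)
  scheme
}

#' @rdname read_threshold_scheme
#' @export
write_threshold_scheme <- function(scheme, path) {
  validate_threshold_scheme(scheme)
  out <- lapply(seq_len(nrow(scheme)), function(i)
    list(lo = scheme$lo[i], hi = scheme$hi[i],
         compartment = scheme$compartment[i]))
  names(out) <- scheme$tissue
  yaml::write_yaml(out, path)
  invisible(path)
}
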