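# Minimal single-frame DICOM codec (Explicit VR Little Endian).
#
# Covers exactly what an L3 body-composition pipeline needs from a
# secondary-capture CT file: Rows/Columns, PixelSpacing, RescaleSlope and
# RescaleIntercept, PatientID, AcquisitionDate and 16-bit PixelData. Files
# written here are standard enough to be read back by pydicom; reading
# supports any Explicit-VR-Little-Endian single-frame file carrying those
# tags. Compressed transfer syntaxes, sequences and multi-frame objects are
# rejected with explicit errors.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"   # secondary capture
DICOM_ROOT_UID <- "1.2.826.0.1.3680043.10.1463"

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")

# VRs whose explicit form uses a 2-byte reserved field + 4-byte length.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dicom_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  stopifnot(is.raw(value), length(value) %% 2L == 0L)
  len <- if (vr %in% LONG_VRS) c(as.raw(c(0L, 0L)), uint32_raw(length(value)))
         else uint16_raw(length(value))
  c(uint16_raw(group), uint16_raw(element), charToRaw(vr), len, value)
}

# Format a number as a DICOM DS string (<= 16 chars).
ds_string <- function(x) formatC(x, format = "fg", digits = 10, width = 1)

#' Write a CT slice as a single-frame DICOM file
#'
#' Emits a secondary-capture-style CT object in Explicit VR Little Endian
#' with 16-bit unsigned stored pixels, `RescaleSlope = 1` and
#' `RescaleIntercept = -1024`, so stored values are `HU + 1024` (all
#' non-negative after the container's clamping to \eqn{[-1024, 3071]}).
#'
#' @param slice a [ct_slice()].
#' @param path output file path (conventionally `.dcm`).
#' @return `path`, invisibly.
#' @seealso [read_ct_slice()]
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  px <- slice$pixels
  intercept <- -1024L
  stored <- as.integer(t(px)) - intercept   # row-major, all in [0, 4095]

  sop_uid <- paste0(DICOM_ROOT_UID, ".",
                    sum(as.double(stored) * seq_along(stored)) %% 1e8, ".",
                    nrow(px), ".", ncol(px))
  date_str <- if (!is.na(slice$acquisition_date))
    format(slice$acquisition_date, "%Y%m%d") else ""

  meta <- c(
    dicom_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002L, 0x0002L, "UI", SC_SOP_CLASS),
    dicom_element(0x0002L, 0x0003L, "UI", sop_uid),
    dicom_element(0x0002L, 0x0010L, "UI", DICOM_EXPLICIT_LE),
    dicom_element(0x0002L, 0x0012L, "UI", paste0(DICOM_ROOT_UID, ".1"))
  )
  pid <- slice$patient_id
  if (is.na(pid)) pid <- ""
  body <- c(
    dicom_element(0x0008L, 0x0016L, "UI", SC_SOP_CLASS),
    dicom_element(0x0008L, 0x0018L, "UI", sop_uid),
    dicom_element(0x0008L, 0x0022L, "DA", date_str),
    dicom_element(0x0008L, 0x0060L, "CS", "CT"),
    dicom_element(0x0010L, 0x0020L, "LO", pid),
    dicom_element(0x0028L, 0x0002L, "US", uint16_raw(1L)),
    dicom_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dicom_element(0x0028L, 0x0010L, "US", uint16_raw(nrow(px))),
    dicom_element(0x0028L, 0x0011L, "US", uint16_raw(ncol(px))),
    dicom_element(0x0028L, 0x0030L, "DS",
                  paste(ds_string(slice$pixel_spacing[1]),
                        ds_string(slice$pixel_spacing[2]), sep = "\\")),
    dicom_element(0x0028L, 0x0100L, "US", uint16_raw(16L)),
    dicom_element(0x0028L, 0x0101L, "US", uint16_raw(16L)),
    dicom_element(0x0028L, 0x0102L, "US", uint16_raw(15L)),
    dicom_element(0x0028L, 0x0103L, "US", uint16_raw(0L)),
    dicom_element(0x0028L, 0x1052L, "DS", ds_string(intercept)),
    dicom_element(0x0028L, 0x1053L, "DS", ds_string(1)),
    dicom_element(0x7FE0L, 0x0010L, "OW",
                  writeBin(stored, raw(), size = 2L, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(dicom_element(0x0002L, 0x0000L, "UL", uint32_raw(length(meta))),
             meta, body), con)
  invisible(path)
}

# Parse all data elements of an Explicit-VR-LE byte stream into a list keyed
# by "group,element" (hex), each entry list(vr, bytes).
parse_dicom_elements <- function(bytes, offset) {
  out <- list()
  i <- offset
  n <- length(bytes)
  while (i + 8L <= n) {
    grp <- readBin(bytes[i + 1:2], "integer", size = 2L, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[i + 3:4], "integer", size = 2L, signed = FALSE,
                   endian = "little")
    vr <- rawToChar(bytes[i + 5:6])
    if (!grepl("^[A-Z]{2}$", vr))
      stopf("unsupported DICOM encoding at byte %d (implicit VR or compressed transfer syntax?)", i)
    if (vr %in% LONG_VRS) {
      len <- readBin(bytes[i + 9:12], "integer", size = 4L, endian = "little")
      i <- i + 12L
    } else {
      len <- readBin(bytes[i + 7:8], "integer", size = 2L, signed = FALSE,
                     endian = "little")
      i <- i + 8L
    }
    if (vr == "SQ") stopf("DICOM sequences are not supported by this reader")
    if (len < 0L || i + len > n) stopf("truncated DICOM element (%04X,%04X)", grp, ele)
    key <- sprintf("%04X,%04X", grp, ele)
    out[[key]] <- list(vr = vr, bytes = bytes[i + seq_len(len)])
    i <- i + len
  }
  out
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el$bytes), useBytes = TRUE))
}

dicom_numbers <- function(el) {
  s <- dicom_string(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' Read a single-frame CT DICOM file
#'
#' Parses an Explicit VR Little Endian single-frame DICOM file and converts
#' stored pixel values to Hounsfield units as
#' `HU = stored * RescaleSlope + RescaleIntercept` (exact integer arithmetic
#' when the slope is 1). Missing `PixelSpacing` or rescale tags are hard
#' errors -- without them, areas in cm^2 would be meaningless. Multi-frame
#' objects are rejected with a pointer to extract a single slice upstream.
#'
#' @param path DICOM file path.
#' @return a [ct_slice()].
#' @export
read_ct_slice <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 200L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stopf("%s is not a DICOM file (missing DICM magic)", path)
  els <- parse_dicom_elements(bytes, 132L)

  ts <- dicom_string(els[["0002,0010"]])
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE)
    stopf("unsupported transfer syntax %s (only Explicit VR Little Endian)", ts)

  nframes <- dicom_string(els[["0028,0008"]])
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stopf("multi-frame DICOM (%s frames): extract the single L3 slice first",
          nframes)

  rows <- readBin(els[["0028,0010"]]$bytes, "integer", size = 2L,
                  signed = FALSE, endian = "little")
  cols <- readBin(els[["0028,0011"]]$bytes, "integer", size = 2L,
                  signed = FALSE, endian = "little")
  spacing <- dicom_numbers(els[["0028,0030"]])
  if (is.null(spacing) || length(spacing) != 2L)
    stopf("PixelSpacing (0028,0030) missing: areas would be meaningless")
  slope <- dicom_numbers(els[["0028,1053"]])
  intercept <- dicom_numbers(els[["0028,1052"]])
  if (is.null(slope) || is.null(intercept))
    stopf("RescaleSlope/RescaleIntercept (0028,1053/1052) missing: cannot convert to HU")

  pd <- els[["7FE0,0010"]]
  if (is.null(pd)) stopf("no PixelData (7FE0,0010) in %s", path)
  bits <- readBin(els[["0028,0100"]]$bytes, "integer", size = 2L,
                  signed = FALSE, endian = "little")
  if (bits != 16L) stopf("only 16-bit PixelData supported (got %d)", bits)
  pixrep <- if (!is.null(els[["0028,0103"]]))
    readBin(els[["0028,0103"]]$bytes, "integer", size = 2L, signed = FALSE,
            endian = "little") else 0L
  stored <- readBin(pd$bytes, "integer", n = rows * cols, size = 2L,
                    signed = (pixrep == 1L), endian = "little")
  if (length(stored) != rows * cols)
    stopf("PixelData length %d does not match %d x %d", length(stored), rows, cols)

  hu <- stored * slope + intercept
  if (slope == 1) storage.mode(hu) <- "integer"
  px <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)

  date_str <- dicom_string(els[["0008,0022"]])
  acq <- if (!is.null(date_str) && nzchar(date_str))
    as.Date(date_str, format = "%Y%m%d") else as.Date(NA)
  pid <- dicom_string(els[["0010,0020"]]) %||% NA_character_
  if (identical(pid, "")) pid <- NA_character_

  ct_slice(round(px), pixel_spacing = spacing, patient_id = pid,
           acquisition_date = acq)
}
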