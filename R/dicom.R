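# Minimal single-frame CT DICOM support: explicit-VR little-endian transfer
# syntax only, which is what this package's own writer emits and what the
# study's converted slices use. Covers exactly the attributes the model
# pipeline needs (geometry, rescale, identity, pixel data); anything fancier
# (compressed syntaxes, multi-frame, RT structure sets) is out of scope.
#
# DICOM pixel data is stored row-major (whole rows, top to bottom); R
# matrices are column-major, so the pixel block is transposed on both paths.

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_uint16 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")

# read one explicit-VR element; returns list(group, element, vr, bytes) or NULL at EOF
.dcm_read_element <- function(con) {
  group <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  if (length(group) == 0L) return(NULL)
  element <- .dcm_uint16(con)
  vr <- rawToChar(readBin(con, "raw", 2L))
  if (!grepl("^[A-Z]{2}$", vr)) {
    stop("DICOM format error: expected explicit VR at tag (",
         sprintf("%04X,%04X", group, element), "); only explicit-VR ",
         "little-endian files are supported", call. = FALSE)
  }
  if (vr %in% .dcm_long_vrs) {
    readBin(con, "raw", 2L)  # reserved
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    len <- .dcm_uint16(con)
  }
  bytes <- if (len > 0L) readBin(con, "raw", len) else raw(0)
  list(group = group, element = element, vr = vr, bytes = bytes)
}

.dcm_text <- function(el) {
  bytes <- el$bytes[el$bytes != as.raw(0L)]   # UI values are nul-padded
  sub(" +$", "", rawToChar(bytes))
}

.dcm_us <- function(el) readBin(el$bytes, "integer", 1L, size = 2L, signed = FALSE, endian = "little")

#' Read a single-frame CT DICOM slice
#'
#' Parses an explicit-VR little-endian DICOM file and returns HU values,
#' i.e. stored pixel values after applying the file's rescale slope and
#' intercept. Only monochrome images are accepted.
#'
#' @param path DICOM file path.
#' @return A [ct_image()].
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 132L)
  if (length(head) < 132L || rawToChar(head[129:132]) != "DICM") {
    # no preamble: rewind and parse from the start
    close(con)
    con <- file(path, "rb")
  }
  tags <- list()
  repeat {
    el <- .dcm_read_element(con)
    if (is.null(el)) break
    key <- sprintf("%04X,%04X", el$group, el$element)
    tags[[key]] <- el
    if (key == "7FE0,0010") break
  }
  need <- function(key, name) {
    if (is.null(tags[[key]])) {
      stop("DICOM format error: missing ", name, " (", key, ")", call. = FALSE)
    }
    tags[[key]]
  }
  photometric <- if (!is.null(tags[["0028,0004"]])) .dcm_text(tags[["0028,0004"]]) else "MONOCHROME2"
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2")) {
    stop("DICOM format error: PhotometricInterpretation '", photometric,
         "' is not monochrome", call. = FALSE)
  }
  rows <- .dcm_us(need("0028,0010", "Rows"))
  cols <- .dcm_us(need("0028,0011", "Columns"))
  bits <- if (!is.null(tags[["0028,0100"]])) .dcm_us(tags[["0028,0100"]]) else 16L
  if (bits != 16L) stop("DICOM format error: BitsAllocated must be 16, got ", bits, call. = FALSE)
  signed <- !is.null(tags[["0028,0103"]]) && .dcm_us(tags[["0028,0103"]]) == 1L
  slope <- if (!is.null(tags[["0028,1053"]])) as.numeric(.dcm_text(tags[["0028,1053"]])) else 1
  intercept <- if (!is.null(tags[["0028,1052"]])) as.numeric(.dcm_text(tags[["0028,1052"]])) else 0
  px <- need("7FE0,0010", "PixelData")
  if (length(px$bytes) < 2L * rows * cols) {
    stop("DICOM format error: PixelData has ", length(px$bytes),
         " bytes, expected ", 2L * rows * cols, call. = FALSE)
  }
  stored <- readBin(px$bytes, "integer", rows * cols, size = 2L,
                    signed = signed, endian = "little")
  hu <- matrix(stored * slope + intercept, rows, cols, byrow = TRUE)
  spacing <- NULL
  if (!is.null(tags[["0028,0030"]])) {
    spacing <- as.numeric(strsplit(.dcm_text(tags[["0028,0030"]]), "\\\\")[[1]])
  }
  pid <- if (!is.null(tags[["0010,0020"]])) .dcm_text(tags[["0010,0020"]]) else "unknown"
  slice <- if (!is.null(tags[["0020,0013"]])) as.integer(.dcm_text(tags[["0020,0013"]])) else 0L
  ct_image(hu, patient_id = pid, slice_index = slice, pixel_spacing = spacing)
}

.dcm_pad <- function(bytes, pad = as.raw(0L)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dcm_element <- function(group, element, vr, bytes) {
  bytes <- .dcm_pad(bytes, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  head <- c(writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2L, endian = "little"),
            charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0L, 0L)),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  } else {
    c(head, writeBin(length(bytes), raw(), size = 2L, endian = "little"), bytes)
  }
}

.dcm_str_element <- function(group, element, vr, value) {
  .dcm_element(group, element, vr, charToRaw(as.character(value)))
}

.dcm_us_element <- function(group, element, value) {
  .dcm_element(group, element, "US", writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
}

#' Write a CT slice as a single-frame DICOM file
#'
#' Emits an explicit-VR little-endian file with a standard preamble and file
#' meta group. Stored values are `(HU - intercept) / slope` rounded to the
#' nearest integer, so integer-valued HU arrays round-trip bit-exactly with
#' the default identity slope.
#'
#' @param img A [ct_image()] or HU matrix.
#' @param path Output path.
#' @param slope,intercept Rescale slope/intercept written to the file.
#' @export
write_dicom_slice <- function(img, path, slope = 1, intercept = -1024) {
  if (inherits(img, "ct_image")) {
    hu <- img$pixels; pid <- img$patient_id; slice <- img$slice_index
    spacing <- img$pixel_spacing %||% c(1, 1)
  } else {
    hu <- img; pid <- "unknown"; slice <- 0L; spacing <- c(1, 1)
  }
  stored <- round((hu - intercept) / slope)
  if (any(stored < -32768 | stored > 32767)) {
    stop("stored values exceed int16 range; adjust slope/intercept", call. = FALSE)
  }
  # row-major pixel block
  px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")

  sop_instance <- paste0("1.2.826.0.1.3680043.8.498.", abs(sum(stored)) %% 1e8, ".", nrow(hu))
  meta <- c(
    .dcm_str_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_str_element(0x0002, 0x0003, "UI", sop_instance),
    .dcm_str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  group_len <- .dcm_element(0x0002, 0x0000, "UL",
                            writeBin(length(meta), raw(), size = 4L, endian = "little"))
  body <- c(
    .dcm_str_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_str_element(0x0008, 0x0018, "UI", sop_instance),
    .dcm_str_element(0x0010, 0x0020, "LO", pid),
    .dcm_str_element(0x0020, 0x0013, "IS", as.character(slice)),
    .dcm_us_element(0x0028, 0x0002, 1L),
    .dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_us_element(0x0028, 0x0010, nrow(hu)),
    .dcm_us_element(0x0028, 0x0011, ncol(hu)),
    .dcm_str_element(0x0028, 0x0030, "DS", paste(format(spacing, trim = TRUE), collapse = "\\")),
    .dcm_us_element(0x0028, 0x0100, 16L),
    .dcm_us_element(0x0028, 0x0101, 16L),
    .dcm_us_element(0x0028, 0x0102, 15L),
    .dcm_us_element(0x0028, 0x0103, 1L),
    .dcm_str_element(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    .dcm_str_element(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    .dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), group_len, meta, body), con)
  invisible(path)
}
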