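# Minimal DICOM reader: single-frame, monochrome, uncompressed pixel data,
# little-endian implicit or explicit VR (transfer syntaxes 1.2.840.10008.1.2
# and 1.2.840.10008.1.2.1).  Sufficient for plain AP radiograph exports; it
# is not a general DICOM implementation.

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && identical(rawToChar(hdr[129:132]), "DICM")
}

read_u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
read_u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

# VRs whose explicit form carries a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read pixel data from a single-frame monochrome DICOM file
#'
#' Parses the little-endian data set, extracts Rows, Columns, BitsAllocated,
#' PhotometricInterpretation and PixelData, and rescales stored values to
#' \[0, 1\] by the maximum representable value of the allocated sample width
#' (so a 16-bit image with maximum stored value 4095 maps to 4095/65535).
#' MONOCHROME1 images are inverted so that bone is bright.
#'
#' @param path path to a DICOM file (128-byte preamble + "DICM").
#' @return numeric matrix of intensities in \[0, 1\], row-major.
#' @export
read_dicom_pixels <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  buf <- readBin(con, "raw", sz)
  if (length(buf) < 140 || !identical(rawToChar(buf[129:132]), "DICM"))
    stop("not a DICOM file (missing DICM magic): ", path)

  pos <- 133L  # first byte after the magic
  explicit <- TRUE   # file meta group (0002) is always explicit
  transfer_syntax <- "1.2.840.10008.1.2.1"
  fields <- list()
  pixel_raw <- NULL

  while (pos + 7L <= length(buf)) {
    group <- read_u16(buf[pos:(pos + 1L)])
    elem  <- read_u16(buf[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    exp_here <- if (group == 0x0002) TRUE else explicit
    if (exp_here) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(buf[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_u16(buf[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_u32(buf[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    val <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len

    if (group == 0x0002 && elem == 0x0010) {
      transfer_syntax <- sub("\\s+$", "", rawToChar(val))
      transfer_syntax <- gsub("\\x00", "", transfer_syntax, useBytes = TRUE)
      if (transfer_syntax == "1.2.840.10008.1.2") explicit <- FALSE
      else if (transfer_syntax != "1.2.840.10008.1.2.1")
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
    } else if (group == 0x0028) {
      key <- sprintf("%04x", elem)
      if (key %in% c("0002", "0010", "0011", "0100", "0101", "0103"))
        fields[[key]] <- read_u16(val[1:2])
      if (key == "0004")
        fields[[key]] <- toupper(sub("\\s+$", "", rawToChar(val)))
    } else if (group == 0x7FE0 && elem == 0x0010) {
      pixel_raw <- val
    }
  }

  rows <- fields[["0010"]]; cols <- fields[["0011"]]
  bits <- fields[["0100"]] %||% 16L
  spp  <- fields[["0002"]] %||% 1L
  if (is.null(rows) || is.null(cols) || is.null(pixel_raw))
    stop("DICOM file lacks Rows/Columns/PixelData: ", path)
  if (spp > 3) stop("rejected: DICOM image has ", spp, " samples per pixel (more than 3)")
  if (spp != 1) stop("only monochrome DICOM images are supported")

  vals <- if (bits <= 8) {
    as.numeric(pixel_raw[seq_len(rows * cols)])
  } else {
    ints <- readBin(pixel_raw, "integer", n = rows * cols, size = 2,
                    signed = FALSE, endian = "little")
    as.numeric(ints)
  }
  px <- matrix(vals / (2^bits - 1), nrow = rows, ncol = cols, byrow = TRUE)
  if (identical(fields[["0004"]], "MONOCHROME1")) px <- 1 - px
  pmin(pmax(px, 0), 1)
}
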