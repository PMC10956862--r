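# Fixtures are generated in code at test time; nothing binary is stored.

# dark frame with a bright vertical band (0-based column limits, inclusive)
band_image <- function(side = 256, col_lo = 108, col_hi = 147,
                       fg = 0.9, bg = 0) {
  m <- matrix(bg, side, side)
  m[, (col_lo + 1):(col_hi + 1)] <- fg
  m
}

quantize8 <- function(x) round(x * 255) / 255

# minimal single-frame monochrome DICOM writer (little-endian), used to
# exercise the reader; values are 16-bit unsigned
write_test_dicom <- function(path, values, rows, cols, explicit = TRUE,
                             photometric = "MONOCHROME2") {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  str_even <- function(s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    s
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  short_el <- function(group, elem, vr, payload_fun, len, meta = FALSE) {
    u16(group); u16(elem)
    if (meta || explicit) {
      writeChar(vr, con, eos = NULL)
      u16(len)
    } else u32(len)
    payload_fun()
  }
  ts <- "1.2.840.10008.1.2.1"
  if (!explicit) ts <- "1.2.840.10008.1.2"
  ts_pad <- nchar(ts) %% 2 == 1     # UI values pad to even length with NUL
  ts_len <- nchar(ts) + ts_pad
  short_el(0x0002, 0x0010, "UI", function() {
    writeChar(ts, con, eos = NULL)
    if (ts_pad) writeBin(raw(1), con)
  }, ts_len, meta = TRUE)
  short_el(0x0028, 0x0002, "US", function() u16(1), 2)
  pm <- str_even(photometric)
  short_el(0x0028, 0x0004, "CS", function() writeChar(pm, con, eos = NULL),
           nchar(pm))
  short_el(0x0028, 0x0010, "US", function() u16(rows), 2)
  short_el(0x0028, 0x0011, "US", function() u16(cols), 2)
  short_el(0x0028, 0x0100, "US", function() u16(16), 2)
  short_el(0x0028, 0x0101, "US", function() u16(12), 2)
  short_el(0x0028, 0x0103, "US", function() u16(0), 2)
  # pixel data: OW with reserved + 4-byte length in explicit form
  u16(0x7FE0); u16(0x0010)
  if (explicit) {
    writeChar("OW", con, eos = NULL); u16(0)
    u32(2 * length(values))
  } else u32(2 * length(values))
  u16(values)
  invisible(path)
}

# circular-arc center curve as a center_curve object (odd sample count so
# the apex is an exact sample); chord vertical, bow toward lower columns
arc_curve <- function(phi_deg, chord = 200, x0 = 150, r0 = 10, n = 1001) {
  phi <- phi_deg * pi / 180
  R <- chord / (2 * sin(phi / 2))
  yc <- r0 + chord / 2
  xc <- x0 + R * cos(phi / 2)
  r <- seq(r0, r0 + chord, length.out = n)
  center_curve(r, xc - sqrt(R^2 - (r - yc)^2))
}
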