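# Minimal single-strip little-endian float TIFF writer, used only to
# fabricate the third-party "float-valued label map" dialect that the R tiff
# package can read but not write.
write_float_tiff <- function(m, path) {
  nr <- nrow(m); nc <- ncol(m)
  data <- writeBin(as.numeric(t(m)), raw(), size = 4, endian = "little")
  data_offset <- 8L
  ifd_offset <- data_offset + length(data)

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  # tag: id, type (3 = SHORT, 4 = LONG), count 1, value
  tag <- function(id, type, value) {
    v <- if (type == 3) c(u16(value), u16(0)) else u32(value)
    c(u16(id), u16(type), u32(1), v)
  }
  tags <- list(
    tag(256, 4, nc),                 # ImageWidth
    tag(257, 4, nr),                 # ImageLength
    tag(258, 3, 32),                 # BitsPerSample
    tag(259, 3, 1),                  # Compression: none
    tag(262, 3, 1),                  # Photometric: BlackIsZero
    tag(273, 4, data_offset),        # StripOffsets
    tag(277, 3, 1),                  # SamplesPerPixel
    tag(278, 4, nr),                 # RowsPerStrip
    tag(279, 4, length(data)),       # StripByteCounts
    tag(339, 3, 3)                   # SampleFormat: IEEE float
  )
  header <- c(charToRaw("II"), u16(42), u32(ifd_offset))
  ifd <- c(u16(length(tags)), unlist(tags), u32(0))
  writeBin(c(header, data, ifd), path)
  invisible(path)
}
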