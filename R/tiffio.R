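# Minimal baseline TIFF I/O for single-plane 16-bit grayscale images.
#
# No TIFF package is available in the target environment, so the package
# carries its own writer/reader for the one dialect it produces: baseline
# TIFF, little-endian, uncompressed, one strip, 16 bits per sample, one
# sample per pixel. read_tiff() only accepts files of that dialect.

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' @param img numeric matrix; values are clamped to \[0, 65535\] and rounded.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  h <- nrow(img)
  w <- ncol(img)
  px <- as.integer(round(pmin(pmax(t(img), 0), 65535)))  # row-major
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  u16(42L)
  u32(8L)                      # IFD offset
  n_tags <- 8L
  data_off <- 8L + 2L + n_tags * 12L + 4L   # pixel data right after IFD
  u16(n_tags)
  tag <- function(id, type, count, value) {
    u16(id); u16(type); u32(count); u32(value)
  }
  tag(256L, 3L, 1L, w)                 # ImageWidth
  tag(257L, 3L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, 16L)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression: none
  tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_off)          # StripOffsets
  tag(278L, 3L, 1L, h)                 # RowsPerStrip
  tag(279L, 4L, 1L, 2L * w * h)        # StripByteCounts
  u32(0L)                              # next IFD: none
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff()]
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II"))
    stop("not a little-endian TIFF: ", path)
  r16 <- function() readBin(con, "integer", 1, size = 2, endian = "little",
                            signed = FALSE)
  r32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  if (r16() != 42L) stop("bad TIFF magic in ", path)
  ifd <- r32()
  seek(con, ifd)
  n <- r16()
  tags <- list()
  for (i in seq_len(n)) {
    id <- r16(); r16(); r32()
    tags[[as.character(id)]] <- r32()
  }
  need <- c("256", "257", "273", "279")
  if (!all(need %in% names(tags))) stop("unsupported TIFF layout in ", path)
  if (!identical(tags[["258"]] %||% 16L, 16L) ||
      !identical(tags[["259"]] %||% 1L, 1L))
    stop("only uncompressed 16-bit grayscale TIFF is supported: ", path)
  w <- tags[["256"]]; h <- tags[["257"]]
  seek(con, tags[["273"]])
  px <- readBin(con, "integer", w * h, size = 2, endian = "little",
                signed = FALSE)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
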