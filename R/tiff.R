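# Minimal baseline TIFF support for single-channel grayscale images.
#
# The quantification index operates on raw 8- or 16-bit grayscale
# micrographs; no TIFF package is available in the target environment, so
# this file implements the small baseline subset the pipeline needs:
# uncompressed, one sample per pixel, 8 or 16 bits, any number of strips on
# read, one strip on write. Written files are little-endian ("II"); both
# byte orders are accepted on read. Anything fancier (compression, tiles,
# palettes, multi-page) is refused with a clear error rather than guessed at.

TIFF_TAG <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples = 277L,
  rows_per_strip = 278L, strip_bytes = 279L
)

#' Read a single-channel grayscale TIFF
#'
#' Reads an uncompressed 8- or 16-bit single-sample grayscale TIFF into an
#' integer matrix (rows = image rows). Compressed, tiled, paletted or
#' multi-sample files are rejected: channel identity is semantic in this
#' pipeline (marker vs nuclei), so no implicit conversion is ever applied.
#'
#' @param path path to a TIFF file.
#' @return integer matrix with attributes `bit_depth` (8 or 16).
#' @seealso [write_gray_tiff()], [fluor_image()]
#' @export
read_gray_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file (too short): ", path)
  order_mark <- rawToChar(raw_all[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd_int <- function(off, size, n = 1L) {
    # signed=FALSE is only valid for 1- and 2-byte reads; 4-byte LONGs are
    # read signed and lifted (offsets in files this writer/readers handle
    # stay far below 2^31 anyway)
    v <- if (size <= 2) {
      readBin(raw_all[(off + 1):(off + size * n)], "integer",
              n = n, size = size, endian = endian, signed = FALSE)
    } else {
      readBin(raw_all[(off + 1):(off + size * n)], "integer",
              n = n, size = size, endian = endian)
    }
    ifelse(v < 0, v + 2^32, v)
  }
  if (rd_int(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- rd_int(4, 4)
  n_entries <- rd_int(ifd, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd_int(e, 2)
    type <- rd_int(e + 2, 2)
    count <- rd_int(e + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[type]      # BYTE, ASCII, SHORT, LONG
    if (is.na(size) || type > 4) next     # skip rational/other tag types
    vals <- if (size * count <= 4) {
      rd_int(e + 8, size, count)
    } else {
      rd_int(rd_int(e + 8, 4), size, count)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAG[[tag]])]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag: ", tag)
      default
    } else v
  }
  if (need("compression", 1L)[1] != 1L)
    stop("only uncompressed TIFF is supported: ", path)
  if (need("samples", 1L)[1] != 1L)
    stop("only single-sample (grayscale) TIFF is supported; ",
         "extract the relevant channel explicitly: ", path)
  bits <- need("bits")[1]
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth ", bits, ": ", path)
  w <- need("width")[1]; h <- need("length")[1]
  offs <- need("strip_offsets"); nbytes <- need("strip_bytes")
  bytes_per <- bits %/% 8L
  px <- unlist(lapply(seq_along(offs), function(s) {
    readBin(raw_all[(offs[s] + 1):(offs[s] + nbytes[s])], "integer",
            n = nbytes[s] %/% bytes_per, size = bytes_per,
            endian = endian, signed = FALSE)
  }))
  if (length(px) != w * h) stop("TIFF pixel data truncated: ", path)
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  attr(m, "bit_depth") <- as.integer(bits)
  m
}

#' Write a single-channel grayscale TIFF
#'
#' Writes an integer matrix as an uncompressed little-endian baseline TIFF,
#' one strip, one sample per pixel.
#'
#' @param pixels integer matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(pixels, path, bit_depth = 16L) {
  bit_depth <- as.integer(bit_depth)
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxv))
    stop("pixel values out of range for ", bit_depth, "-bit TIFF")
  h <- nrow(pixels); w <- ncol(pixels)
  bytes_per <- bit_depth %/% 8L
  data_bytes <- w * h * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  # Layout: 8-byte header | IFD | pixel data; the IFD therefore sits at 8.
  writeChar("II", con, eos = NULL); wr(42, 2); wr(8, 4)
  n_tags <- 9L
  ifd_len <- 2 + n_tags * 12 + 4
  data_off <- 8 + ifd_len
  entry <- function(tag, type, count, value) {
    wr(tag, 2); wr(type, 2); wr(count, 4)
    if (type == 3) { wr(value, 2); wr(0, 2) } else wr(value, 4)
  }
  wr(n_tags, 2)
  entry(TIFF_TAG[["width"]], 3, 1, w)
  entry(TIFF_TAG[["length"]], 3, 1, h)
  entry(TIFF_TAG[["bits"]], 3, 1, bit_depth)
  entry(TIFF_TAG[["compression"]], 3, 1, 1)          # none
  entry(TIFF_TAG[["photometric"]], 3, 1, 1)          # BlackIsZero
  entry(TIFF_TAG[["strip_offsets"]], 4, 1, data_off)
  entry(TIFF_TAG[["samples"]], 3, 1, 1)
  entry(TIFF_TAG[["rows_per_strip"]], 3, 1, h)
  entry(TIFF_TAG[["strip_bytes"]], 4, 1, data_bytes)
  wr(0, 4)                                           # no next IFD
  v <- as.integer(t(pixels))                         # row-major
  if (bytes_per == 2L) v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(v, con, size = bytes_per, endian = "little")
  invisible(path)
}
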