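# 16-bit grayscale PNG writer.
#
# The PNG writers available to this package emit 8 bits per sample for
# grayscale, so the dataset writer's 16-bit image files are produced by this
# minimal encoder: one IHDR (bit depth 16, color type 0), one IDAT holding
# zlib-compressed scanlines with filter type 0, and IEND. Reading goes
# through png::readPNG, which fully supports 16-bit grayscale and serves as
# the round-trip check in the test suite.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320 (signed), logical shift
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L), crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

u32_bytes <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- as.numeric(crc32(body)) %% 4294967296
  c(u32_bytes(length(data)), body, u32_bytes(crc))
}

#' Write a grayscale image as a 16-bit PNG
#'
#' Quantizes an `[0, 1]` image matrix to 16 bits and writes a standard
#' single-channel PNG. The companion reader is [png::readPNG], which returns
#' the values back on the `[0, 1]` scale at 1/65535 resolution. Output is
#' byte-deterministic for a given matrix.
#'
#' @param image Numeric matrix with values in `[0, 1]` (values outside are
#'   clipped); rows index the image's vertical axis.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(image, path) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  img <- pmin(pmax(image, 0), 1)
  v <- round(img * 65535)
  h <- nrow(v); w <- ncol(v)
  rowmaj <- as.vector(t(v))                       # reading order: row by row
  samp <- as.raw(rbind(rowmaj %/% 256, rowmaj %% 256))  # big-endian interleave
  dim(samp) <- c(2L * w, h)
  rows <- rbind(as.raw(0L), samp)                 # filter byte 0 per scanline
  idat <- memCompress(as.raw(rows), type = "gzip")  # zlib (RFC 1950) stream
  ihdr <- c(u32_bytes(w), u32_bytes(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}
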