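# Minimal baseline TIFF 6.0 codec (uncompressed, little-endian) for the
# scanner simulation and scan readers. Supports 8/16-bit grayscale and RGB.
# Deliberately small: no compression, no tiles, no palettes.

#' Digitized film scan
#'
#' Container for a scanned film image: an integer pixel matrix (grayscale)
#' or h x w x 3 array (RGB), the scan resolution and bit depth. Pixel
#' centers sit at `(i - 0.5) * 2.54 / dpi` cm from the image edge.
#'
#' @param pixels integer matrix (rows = y) or h x w x 3 array.
#' @param dpi scan resolution, pixels per inch.
#' @param bit_depth bits per channel (8 or 16).
#' @return object of class `scan_image`.
#' @export
scan_image <- function(pixels, dpi = 300, bit_depth = 16) {
  if (!bit_depth %in% c(8L, 16L)) stop_domain("bit_depth must be 8 or 16")
  check_scalar(dpi, "dpi", positive = TRUE)
  stopifnot(is.array(pixels) || is.matrix(pixels))
  structure(list(pixels = pixels, dpi = dpi, bit_depth = as.integer(bit_depth)),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scan_image> %d x %d px%s, %d-bit, %g dpi (%.2f x %.2f cm)\n",
              d[2], d[1], if (length(d) == 3) " RGB" else "", x$bit_depth,
              x$dpi, d[2] * 2.54 / x$dpi, d[1] * 2.54 / x$dpi))
  invisible(x)
}

scan_channel <- function(image, channel = "red") {
  px <- image$pixels
  if (length(dim(px)) == 3L) {
    i <- match(channel, c("red", "green", "blue"))
    px[, , i]
  } else px
}

pixel_pitch_cm <- function(dpi) 2.54 / dpi

# ---- byte packing -----------------------------------------------------------

u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  r <- raw(2L * length(v))
  r[seq(1L, length(r), 2L)] <- as.raw(v %% 256L)
  r[seq(2L, length(r), 2L)] <- as.raw(v %/% 256L)
  r
}
u32_to_raw <- function(v) {
  v <- as.numeric(v)
  r <- raw(4L * length(v))
  for (k in 0:3) r[seq(1L + k, length(r), 4L)] <- as.raw((v %/% 256^k) %% 256)
  r
}
raw_to_u16 <- function(r) as.integer(r[seq(1L, length(r), 2L)]) +
  256L * as.integer(r[seq(2L, length(r), 2L)])
raw_to_u32 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 4L)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be <= 4 bytes (padded) or an offset
  c(u16_to_raw(tag), u16_to_raw(type), u32_to_raw(count),
    value_raw, raw(4L - length(value_raw)))
}

#' Write a scan image as an uncompressed TIFF
#'
#' Writes baseline little-endian TIFF 6.0: single strip, no compression,
#' grayscale (`PhotometricInterpretation` = BlackIsZero) or RGB, 8 or
#' 16 bits per channel, resolution tags in dpi. Output is byte-identical
#' for identical input (determinism contract of the virtual experiment).
#'
#' @param image a [scan_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path) {
  px <- image$pixels
  rgb <- length(dim(px)) == 3L
  h <- dim(px)[1]; w <- dim(px)[2]
  spp <- if (rgb) 3L else 1L
  bits <- image$bit_depth
  maxv <- 2^bits - 1
  px[px < 0] <- 0; px[px > maxv] <- maxv
  # interleave samples, row-major
  if (rgb) {
    arr <- aperm(px, c(3, 2, 1))      # channel, x, y
  } else {
    arr <- t(px)                       # x, y
  }
  vals <- as.vector(arr)
  data_raw <- if (bits == 16L) u16_to_raw(vals) else as.raw(as.integer(round(vals)))
  n_entries <- 12L
  header_len <- 8L
  # layout: header | bits-array (rgb only) | 2 rationals | pixel data | IFD
  bits_off <- header_len
  bits_raw <- if (rgb) u16_to_raw(rep(bits, 3L)) else raw(0)
  res_off <- bits_off + length(bits_raw)
  res_raw <- c(u32_to_raw(c(round(image$dpi), 1)), u32_to_raw(c(round(image$dpi), 1)))
  data_off <- res_off + length(res_raw)
  ifd_off <- data_off + length(data_raw)
  bits_value <- if (rgb) u32_to_raw(bits_off) else u16_to_raw(bits)
  entries <- c(
    tiff_entry(256L, 4L, 1L, u32_to_raw(w)),                    # ImageWidth
    tiff_entry(257L, 4L, 1L, u32_to_raw(h)),                    # ImageLength
    tiff_entry(258L, 3L, spp, bits_value),                      # BitsPerSample
    tiff_entry(259L, 3L, 1L, u16_to_raw(1L)),                   # Compression=none
    tiff_entry(262L, 3L, 1L, u16_to_raw(if (rgb) 2L else 1L)),  # Photometric
    tiff_entry(273L, 4L, 1L, u32_to_raw(data_off)),             # StripOffsets
    tiff_entry(277L, 3L, 1L, u16_to_raw(spp)),                  # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, u32_to_raw(h)),                    # RowsPerStrip
    tiff_entry(279L, 4L, 1L, u32_to_raw(length(data_raw))),     # StripByteCounts
    tiff_entry(282L, 5L, 1L, u32_to_raw(res_off)),              # XResolution
    tiff_entry(283L, 5L, 1L, u32_to_raw(res_off + 8L)),         # YResolution
    tiff_entry(296L, 3L, 1L, u16_to_raw(2L))                    # ResolutionUnit=inch
  )
  ifd <- c(u16_to_raw(n_entries), entries, u32_to_raw(0))
  out <- c(charToRaw("II"), u16_to_raw(42L), u32_to_raw(header_len),
           bits_raw, res_raw, data_raw, ifd)
  # header promised first IFD right after... we stored offset 8 = bits/res
  # block, so patch the real IFD offset:
  out[5:8] <- u32_to_raw(ifd_off)
  writeBin(out, path)
  invisible(path)
}

#' Read an uncompressed TIFF scan
#'
#' Reads the subset written by [write_tiff()] plus common flatbed output:
#' little-endian baseline TIFF, uncompressed, 8 or 16 bits per channel,
#' grayscale or RGB, one or more strips.
#'
#' @param path TIFF file path.
#' @return a [scan_image()].
#' @export
read_tiff <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(r[1:2])
  if (order == "MM") stop_config("big-endian TIFF is not supported")
  if (order != "II") stop_config("not a TIFF file")
  gu16 <- function(off, n = 1L) raw_to_u16(r[(off + 1L):(off + 2L * n)])
  gu32 <- function(off, n = 1L) raw_to_u32(r[(off + 1L):(off + 4L * n)])
  ifd_off <- gu32(4L)
  n <- gu16(ifd_off)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd_off + 2L + (i - 1L) * 12L
    tag <- gu16(e); type <- gu16(e + 2L); count <- gu32(e + 4L)
    size <- c(1L, 1L, 2L, 4L, 8L)[type]
    if (is.na(size)) next
    total <- size * count
    voff <- if (total > 4L) gu32(e + 8L) else e + 8L
    val <- switch(as.character(type),
      "3" = gu16(voff, count),
      "4" = gu32(voff, count),
      "5" = { x <- gu32(voff, 2L * count); x[seq(1, 2 * count, 2)] / x[seq(2, 2 * count, 2)] },
      as.integer(r[(voff + 1L):(voff + total)]))
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_config(sprintf("TIFF tag %d missing", tag))
      default
    } else v
  }
  if (need(259L, 1L)[1] != 1L) stop_config("only uncompressed TIFF is supported")
  w <- need(256L); h <- need(257L)
  spp <- need(277L, 1L)
  bits <- need(258L)[1]
  if (!bits %in% c(8L, 16L)) stop_config("only 8/16-bit TIFF is supported")
  offs <- need(273L); counts <- need(279L)
  data <- unlist(lapply(seq_along(offs), function(i)
    r[(offs[i] + 1L):(offs[i] + counts[i])]), use.names = FALSE)
  vals <- if (bits == 16L) raw_to_u16(data) else as.integer(data)
  dpi <- need(282L, 300)[1]
  if (spp == 1L) {
    px <- t(matrix(vals, nrow = w))
  } else {
    arr <- array(vals, dim = c(spp, w, h))
    px <- aperm(arr, c(3, 2, 1))
  }
  scan_image(px, dpi = dpi, bit_depth = bits)
}
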