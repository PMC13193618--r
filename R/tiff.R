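# Minimal baseline TIFF support.
#
# No TIFF decoder package is available in the deployment environment, so a
# small reader for the baseline subset that scientific cameras and ImageJ
# commonly emit is provided: uncompressed, chunky (PlanarConfiguration 1),
# 8- or 16-bit, grayscale or RGB, either byte order, strip-organized.
# Anything else (LZW/JPEG compression, tiles, palettes) is rejected with an
# "unsupported image" error. Values are returned normalized to [0,1] like
# png::readPNG, so load_image() treats all decoders uniformly.

read_tiff_baseline <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) rs_error("unsupported image: truncated TIFF",
                                 "reliefstl_unsupported_image")
  endian <- if (raw[1] == as.raw(0x49)) "little" else "big"
  u16 <- function(off) {
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
            endian = endian)
  }
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) rs_error("unsupported image: TIFF offset overflow",
                        "reliefstl_unsupported_image")
    v
  }
  ifd_off <- u32(4L)
  n_entries <- u16(ifd_off)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd_off + 2L + (i - 1L) * 12L
    tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
    size <- c(1L, 1L, 2L, 4L, 8L)[type]  # BYTE ASCII SHORT LONG RATIONAL
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4L) e + 8L else u32(e + 8L)
    vals <- if (type == 3L) {
      vapply(seq_len(count) - 1L, function(k) u16(voff + 2L * k), 0)
    } else if (type == 4L) {
      vapply(seq_len(count) - 1L, function(k) u32(voff + 4L * k), 0)
    } else NULL
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default))
        rs_error(sprintf("unsupported image: TIFF missing tag %d", tag),
                 "reliefstl_unsupported_image")
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8L); spp <- need(277, 1L)
  compression <- need(259, 1L); planar <- need(284, 1L)
  offsets <- need(273); counts <- need(279)
  rows_per_strip <- need(278, height)
  if (compression != 1L || planar != 1L)
    rs_error("unsupported image: only uncompressed chunky TIFF is supported",
             "reliefstl_unsupported_image")
  if (!all(bits == bits[1]) || !(bits[1] %in% c(8L, 16L)))
    rs_error("unsupported image: TIFF must be 8- or 16-bit",
             "reliefstl_unsupported_image")
  bits <- bits[1]
  if (!(spp %in% c(1L, 3L)))
    rs_error("unsupported image: TIFF must be grayscale or RGB",
             "reliefstl_unsupported_image")
  payload <- raw(0)
  for (s in seq_along(offsets)) {
    payload <- c(payload, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
  }
  n_samples <- width * height * spp
  samples <- if (bits == 8L) {
    as.integer(payload[seq_len(n_samples)])
  } else {
    readBin(payload, "integer", n = n_samples, size = 2, signed = FALSE,
            endian = endian)
  }
  if (length(samples) < n_samples)
    rs_error("unsupported image: TIFF strip data shorter than image",
             "reliefstl_unsupported_image")
  maxv <- if (bits == 8L) 255 else 65535
  # chunky layout: sample index = ((row-1)*width + (col-1))*spp + channel
  if (spp == 1L) {
    matrix(samples / maxv, nrow = height, ncol = width, byrow = TRUE)
  } else {
    arr <- array(0, dim = c(height, width, 3L))
    px <- array(samples, dim = c(3L, width, height))
    for (k in 1:3) arr[, , k] <- t(px[k, , ]) / maxv
    arr
  }
}

# Companion writer (single strip, little-endian, uncompressed). Used by the
# test-suite to build TIFF fixtures in code; exported for fixture scripting.
write_tiff_baseline <- function(data, path, bits = 8L) {
  d <- dim(data)
  spp <- if (length(d) == 3L) d[3] else 1L
  height <- d[1]; width <- d[2]
  maxv <- if (bits == 8L) 255L else 65535L
  v <- as.vector(data)
  if (min(v) < 0 || max(v) > maxv || any(v != floor(v)))
    rs_param_error(sprintf("samples must be integers in [0, %d]", maxv))
  # interleave channels row-major
  samples <- if (spp == 1L) {
    as.integer(t(data))
  } else {
    px <- aperm(data, c(3L, 2L, 1L))  # channel, col, row
    as.integer(px)
  }
  payload <- if (bits == 8L) as.raw(samples) else
    writeBin(samples, raw(), size = 2, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L && count == 1L) { w16(value); w16(0L) } else w32(value)
  }
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)
  w32(8L)  # IFD immediately after header
  n_tags <- 11L
  ifd_size <- 2L + n_tags * 12L + 4L
  bits_off <- 8L + ifd_size            # BitsPerSample array when spp == 3
  data_off <- bits_off + (if (spp == 3L) 6L else 0L)
  w16(n_tags)
  entry(256L, 4L, 1L, width)
  entry(257L, 4L, 1L, height)
  if (spp == 1L) entry(258L, 3L, 1L, bits)
  else entry(258L, 3L, 3L, bits_off)
  entry(259L, 3L, 1L, 1L)                      # uncompressed
  entry(262L, 3L, 1L, if (spp == 1L) 1L else 2L)  # BlackIsZero / RGB
  entry(273L, 4L, 1L, data_off)                # strip offset
  entry(277L, 3L, 1L, spp)
  entry(278L, 4L, 1L, height)
  entry(279L, 4L, 1L, length(payload))
  entry(284L, 3L, 1L, 1L)                      # chunky
  entry(339L, 3L, 1L, 1L)                      # unsigned integer samples
  w32(0L)                                      # no next IFD
  if (spp == 3L) { w16(bits); w16(bits); w16(bits) }
  writeBin(payload, con)
  invisible(path)
}
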