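# Image decoding and intensity-grid construction.
#
# Decoded images are stored as 8-bit integer arrays; all downstream stages
# work on a normalized [0,1] intensity grid whose row 1 is the top of the
# photograph.

#' Construct a raster image
#'
#' An 8-bit raster image: an integer array of samples in `[0, 255]` with
#' dimensions `height x width` (grayscale) or `height x width x 3` (RGB).
#' Row 1 is the top row of the photograph.
#'
#' @param data Integer matrix (grayscale) or `h x w x 3` array (RGB) of
#'   samples in `[0, 255]`.
#' @return An object of class `raster_image` with fields `width`, `height`,
#'   `channels` and `data`.
#' @export
raster_image <- function(data) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    rs_param_error("raster image data must be a matrix or h x w x 3 array")
  channels <- if (length(d) == 2L) 1L else as.integer(d[3])
  if (!(channels %in% c(1L, 3L)))
    rs_param_error(sprintf("raster image must have 1 or 3 channels, got %d", channels))
  if (d[1] < 2L || d[2] < 2L)
    rs_error(sprintf("degenerate image: %d x %d (need at least 2 x 2)", d[2], d[1]),
             "reliefstl_degenerate_image")
  v <- as.vector(data)
  if (anyNA(v) || min(v) < 0 || max(v) > 255 || any(v != floor(v)))
    rs_param_error("raster image samples must be integers in [0, 255]")
  storage.mode(data) <- "integer"
  if (length(d) == 3L && channels == 1L) data <- data[, , 1L]
  structure(
    list(width = as.integer(d[2]), height = as.integer(d[1]),
         channels = channels, data = data),
    class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d channel%s, 8-bit\n",
              x$width, x$height, x$channels, if (x$channels > 1) "s" else ""))
  invisible(x)
}

sniff_format <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4 && identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) return("png")
  if (length(magic) >= 2 && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) return("jpeg")
  if (length(magic) >= 4 &&
      (identical(magic, as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(magic, as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))) return("tiff")
  NA_character_
}

# Quantize decoder output in [0,1] to 8-bit. Decoders return k/255 (8-bit)
# or k/65535 (16-bit); round(v * 65535) recovers the integer sample exactly
# in both cases (257*k for 8-bit input), and %/% 257 is the stated 16->8 bit
# reduction, which is the identity on 8-bit input.
quantize8 <- function(v) {
  k16 <- round(v * 65535)
  storage.mode(k16) <- "integer"
  k16 %/% 257L
}

# Composite an alpha channel over a white background, in normalized space.
composite_white <- function(arr) {
  d <- dim(arr)
  nc <- d[3]
  a <- arr[, , nc]
  col <- arr[, , -nc, drop = FALSE]
  out <- array(0, dim = c(d[1], d[2], nc - 1L))
  for (k in seq_len(nc - 1L)) out[, , k] <- col[, , k] * a + (1 - a)
  out
}

#' Load an image file
#'
#' Decodes a PNG, JPEG or baseline TIFF file into an 8-bit [raster_image].
#' 16-bit samples are reduced to 8-bit by integer division by 257; an alpha
#' channel is composited over white and dropped (plate photographs are
#' opaque, and a white backdrop keeps transparent margins low once an
#' inversion choice is made downstream). The format is detected from the
#' file's magic bytes, not its extension.
#'
#' @param path Path to a PNG, JPEG or uncompressed baseline TIFF file.
#' @return A [raster_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path) ||
      dir.exists(path))
    rs_error(sprintf("unsupported image: '%s' (file not found)", path),
             "reliefstl_unsupported_image")
  fmt <- tryCatch(sniff_format(path), error = function(e) NA_character_)
  if (is.na(fmt))
    rs_error(sprintf("unsupported image: '%s' (not PNG, JPEG or TIFF)", path),
             "reliefstl_unsupported_image")
  arr <- tryCatch(
    switch(fmt,
           png = png::readPNG(path),
           jpeg = jpeg::readJPEG(path),
           tiff = read_tiff_baseline(path)),
    error = function(e) {
      # our own conditions (e.g. unsupported TIFF variants) pass through
      if (inherits(e, "reliefstl_error")) stop(e)
      rs_error(sprintf("unsupported image: '%s' (%s)", path, conditionMessage(e)),
               "reliefstl_unsupported_image")
    })
  d <- dim(arr)
  if (any(d[1:2] == 0L))
    rs_error(sprintf("degenerate image: '%s' has a zero dimension", path),
             "reliefstl_degenerate_image")
  if (length(d) == 3L && d[3] %in% c(2L, 4L)) arr <- composite_white(arr)
  d <- dim(arr)
  data <- quantize8(arr)
  if (length(d) == 3L && d[3] == 1L) {
    data <- array(data, dim = d)[, , 1L]
  }
  raster_image(data)
}

#' Construct an intensity grid
#'
#' A normalized scalar field: per-node intensity in `[0, 1]`, row-major with
#' row 1 at the top of the source image.
#'
#' @param values Numeric matrix with all values in `[0, 1]`, at least 2 x 2.
#' @return An object of class `intensity_grid` with fields `rows`, `cols`,
#'   `values`.
#' @export
intensity_grid <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    rs_param_error("intensity grid values must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    rs_param_error("intensity grid must be at least 2 x 2")
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    rs_param_error("intensity grid values must lie in [0, 1]")
  structure(list(rows = nrow(values), cols = ncol(values), values = values),
            class = "intensity_grid")
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("<intensity_grid> %d x %d nodes, range [%.3f, %.3f]\n",
              x$rows, x$cols, min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a raster image to a normalized grayscale grid
#'
#' Grayscale input passes through as `value / 255`; RGB input is reduced
#' with the Rec. 601 luma `Y = 0.299 R + 0.587 G + 0.114 B` (the de-facto
#' default of common image decoders) before normalization.
#'
#' @param img A [raster_image].
#' @return An [intensity_grid] with the same dimensions as `img`.
#' @export
to_grayscale <- function(img) {
  if (!inherits(img, "raster_image"))
    rs_param_error("to_grayscale() expects a raster_image")
  if (img$channels == 1L) {
    v <- img$data / 255
  } else {
    v <- (0.299 * img$data[, , 1L] + 0.587 * img$data[, , 2L] +
            0.114 * img$data[, , 3L]) / 255
  }
  intensity_grid(pmin(pmax(v, 0), 1))
}

# Bilinear resample of a matrix to out_r x out_c, corner-aligned: output
# node j samples input position 1 + (j-1)(n_in-1)/(n_out-1).
bilinear_resample <- function(v, out_r, out_c) {
  in_r <- nrow(v); in_c <- ncol(v)
  pos <- function(n_out, n_in) {
    if (n_out == 1L) return(rep(1, 1L))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  rp <- pos(out_r, in_r); cp <- pos(out_c, in_c)
  r0 <- pmin(floor(rp), in_r - 1L); c0 <- pmin(floor(cp), in_c - 1L)
  fr <- rp - r0; fc <- cp - c0
  v00 <- v[r0, c0, drop = FALSE]; v01 <- v[r0, c0 + 1L, drop = FALSE]
  v10 <- v[r0 + 1L, c0, drop = FALSE]; v11 <- v[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, out_r, out_c); wc <- matrix(fc, out_r, out_c, byrow = TRUE)
  (1 - wr) * (1 - wc) * v00 + (1 - wr) * wc * v01 +
    wr * (1 - wc) * v10 + wr * wc * v11
}

#' Resample an intensity grid to a bounded resolution
#'
#' If the larger grid dimension already fits within `max_dim` the grid is
#' returned unchanged; otherwise the grid is bilinearly resampled so the
#' larger dimension equals `max_dim`, preserving aspect ratio (the other
#' dimension is rounded, minimum 2). Bounding the grid keeps the triangle
#' count of the final solid printable.
#'
#' @param grid An [intensity_grid].
#' @param max_dim Maximum number of nodes along the larger dimension
#'   (default 256, bounding a full plate solid below ~530k triangles).
#' @return An [intensity_grid].
#' @export
resample_grid <- function(grid, max_dim = 256L) {
  if (!inherits(grid, "intensity_grid"))
    rs_param_error("resample_grid() expects an intensity_grid")
  stopifnot_param(is_count(max_dim) && max_dim >= 2,
                  "max_dim must be an integer >= 2")
  r <- grid$rows; c <- grid$cols
  if (max(r, c) <= max_dim) return(grid)
  if (c >= r) {
    out_c <- as.integer(max_dim)
    out_r <- max(2L, as.integer(round(r * max_dim / c)))
  } else {
    out_r <- as.integer(max_dim)
    out_c <- max(2L, as.integer(round(c * max_dim / r)))
  }
  out <- bilinear_resample(grid$values, out_r, out_c)
  intensity_grid(pmin(pmax(out, 0), 1))
}

# Exact-size resample helper used by the slide generator to honour a
# requested physical aspect ratio.
resample_grid_to <- function(grid, out_r, out_c) {
  out <- bilinear_resample(grid$values, as.integer(out_r), as.integer(out_c))
  intensity_grid(pmin(pmax(out, 0), 1))
}
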