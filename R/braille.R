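# Grade-1 (uncontracted) braille embossing.
#
# A braille cell is a 2 x 3 dot grid numbered
#     1 4
#     2 5
#     3 6
# Letters use the standard Grade-1 table; digits reuse the patterns of
# a-j, with each run of digits prefixed by the number sign (dots 3-4-5-6).
# Dimensional defaults follow common tactile-signage practice (~2.5 mm dot
# pitch within a cell, ~6 mm cell-to-cell pitch, 0.5-0.7 mm dot height).

braille_dots_table <- list(
  A = c(1), B = c(1, 2), C = c(1, 4), D = c(1, 4, 5), E = c(1, 5),
  F = c(1, 2, 4), G = c(1, 2, 4, 5), H = c(1, 2, 5), I = c(2, 4),
  J = c(2, 4, 5), K = c(1, 3), L = c(1, 2, 3), M = c(1, 3, 4),
  N = c(1, 3, 4, 5), O = c(1, 3, 5), P = c(1, 2, 3, 4),
  Q = c(1, 2, 3, 4, 5), R = c(1, 2, 3, 5), S = c(2, 3, 4),
  T = c(2, 3, 4, 5), U = c(1, 3, 6), V = c(1, 2, 3, 6),
  W = c(2, 4, 5, 6), X = c(1, 3, 4, 6), Y = c(1, 3, 4, 5, 6),
  Z = c(1, 3, 5, 6))

braille_number_sign <- c(3, 4, 5, 6)

# digit i uses the pattern of the i-th letter a-j (0 -> j)
braille_digit_letter <- c("0" = "J", "1" = "A", "2" = "B", "3" = "C",
                          "4" = "D", "5" = "E", "6" = "F", "7" = "G",
                          "8" = "H", "9" = "I")

# expand text into a list of per-cell dot vectors (NULL = blank cell)
braille_cells <- function(text) {
  chars <- strsplit(toupper(text), "")[[1]]
  bad <- setdiff(unique(chars), c(LETTERS, as.character(0:9), " "))
  if (length(bad) > 0L)
    rs_param_error(sprintf("unsupported braille character(s): %s",
                           paste(sQuote(bad), collapse = ", ")))
  cells <- list()
  in_digits <- FALSE
  for (ch in chars) {
    if (ch %in% names(braille_digit_letter)) {
      if (!in_digits) {
        cells[[length(cells) + 1L]] <- braille_number_sign
        in_digits <- TRUE
      }
      cells[[length(cells) + 1L]] <- braille_dots_table[[braille_digit_letter[[ch]]]]
    } else {
      in_digits <- FALSE
      cells[[length(cells) + 1L]] <- if (ch == " ") numeric(0)
      else braille_dots_table[[ch]]
    }
  }
  cells
}

#' Braille label parameters
#'
#' @param text Label text: letters, digits and spaces. Runs of digits are
#'   automatically prefixed with the braille number sign; at most 20 cells
#'   after that expansion.
#' @param dot_height_mm Emboss height of each dot in mm (default 0.6).
#' @param dot_diameter_mm Dot base diameter in mm (default 1.5).
#' @param dot_pitch_mm Dot-to-dot pitch within a cell in mm (default 2.5).
#' @param cell_pitch_mm Cell-to-cell pitch in mm (default 6.0).
#' @param placement Margin to place the label on: `"bottom"` or `"top"`.
#' @return An object of class `braille_label`.
#' @export
braille_label <- function(text, dot_height_mm = 0.6, dot_diameter_mm = 1.5,
                          dot_pitch_mm = 2.5, cell_pitch_mm = 6.0,
                          placement = c("bottom", "top")) {
  placement <- match.arg(placement)
  stopifnot_param(is.character(text) && length(text) == 1L && nzchar(text),
                  "label text must be a non-empty string")
  for (d in c(dot_height_mm, dot_diameter_mm, dot_pitch_mm, cell_pitch_mm))
    stopifnot_param(is_number(d) && d > 0, "all label dimensions must be > 0")
  cells <- braille_cells(text)  # validates the character set
  if (length(cells) > 20L)
    rs_param_error(sprintf(
      "label is %d braille cells after number-sign expansion (maximum 20)",
      length(cells)))
  structure(list(text = text, dot_height_mm = dot_height_mm,
                 dot_diameter_mm = dot_diameter_mm,
                 dot_pitch_mm = dot_pitch_mm, cell_pitch_mm = cell_pitch_mm,
                 placement = placement),
            class = "braille_label")
}

# physical (width, height) of the label's dot-center lattice in mm
label_extent <- function(label) {
  n <- length(braille_cells(label$text))
  c((n - 1) * label$cell_pitch_mm + label$dot_pitch_mm,
    2 * label$dot_pitch_mm)
}

#' Lay out the dot centers of a braille label
#'
#' Expands the text to Grade-1 cells (digits gain a number-sign cell per
#' digit run) and returns the dot centers, cells left to right. The origin
#' is the center of dot 1 (top-left) of the first cell; y decreases
#' downward within a cell.
#'
#' @param label A [braille_label].
#' @param origin_mm Position `(x, y)` in mm of the first cell's top-left
#'   dot center.
#' @return A data frame with columns `x_mm`, `y_mm`, `cell`, `dot`.
#' @export
text_to_dots <- function(label, origin_mm = c(0, 0)) {
  if (!inherits(label, "braille_label"))
    rs_param_error("text_to_dots() expects a braille_label")
  cells <- braille_cells(label$text)
  p <- label$dot_pitch_mm
  # dot number -> (column, row) offset within the 2 x 3 cell
  dot_col <- c(0, 0, 0, 1, 1, 1) * p
  dot_row <- c(0, 1, 2, 0, 1, 2) * p
  out <- do.call(rbind, lapply(seq_along(cells), function(k) {
    dots <- cells[[k]]
    if (length(dots) == 0L) return(NULL)
    data.frame(x_mm = origin_mm[1] + (k - 1) * label$cell_pitch_mm + dot_col[dots],
               y_mm = origin_mm[2] - dot_row[dots],
               cell = k, dot = dots)
  }))
  if (is.null(out))
    out <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      cell = integer(0), dot = integer(0))
  out
}

#' Emboss braille dots onto a heightmap
#'
#' Raises nodes within `dot_diameter / 2` of each dot center by a
#' spherical-cap profile clamped to `dot_height_mm`
#' (`min(dot_height, sqrt(R^2 - r^2))` with `R = dot_diameter / 2`).
#' Nodes farther than the dot radius from every center are untouched.
#' The grid must resolve the dots: at least 3 nodes must span a dot
#' diameter, and every node under a dot must be included in the mask.
#'
#' @param hm A `heightmap` whose label margin is flat.
#' @param dots Dot centers as returned by [text_to_dots()].
#' @param label The [braille_label] (supplies dot geometry).
#' @return The embossed `heightmap`.
#' @export
emboss_dots <- function(hm, dots, label) {
  if (!inherits(hm, "heightmap")) rs_param_error("expected a heightmap")
  if (!inherits(label, "braille_label"))
    rs_param_error("emboss_dots() expects a braille_label")
  if (nrow(dots) == 0L) return(hm)
  R <- label$dot_diameter_mm / 2
  if (label$dot_diameter_mm / max(hm$dx, hm$dy) < 2)
    rs_error(sprintf(
      "grid too coarse for braille: %.2f mm dots need >= 3 nodes across, spacing is %.2f mm",
      label$dot_diameter_mm, max(hm$dx, hm$dy)),
      "reliefstl_label_resolution")
  x <- node_x(hm); y <- node_y(hm)
  W <- max(x); H <- max(y)
  for (i in seq_len(nrow(dots))) {
    cx <- dots$x_mm[i]; cy <- dots$y_mm[i]
    if (cx < -R || cx > W + R || cy < -R || cy > H + R)
      rs_error(sprintf("braille dot at (%.1f, %.1f) mm lies outside the model",
                       cx, cy), "reliefstl_label_placement")
    d2 <- outer((y - cy)^2, (x - cx)^2, `+`)
    sel <- d2 <= R^2
    if (any(sel & !hm$mask))
      rs_error(sprintf(
        "braille dot at (%.1f, %.1f) mm overlaps masked-out nodes", cx, cy),
        "reliefstl_label_placement")
    add <- pmin(label$dot_height_mm, sqrt(pmax(R^2 - d2, 0)))
    hm$z[sel] <- hm$z[sel] + add[sel]
  }
  hm
}
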