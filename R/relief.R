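# Intensity-to-height conversion: the core of the tactile-model pipeline.
#
# Height is a linear map of normalized intensity over a solid base slab:
#   z = base_thickness + relief_height * e,   e = I or (1 - I) if inverted.
# The map is absolute (I already lies in [0,1] from the 8-bit range), not
# per-image min-max stretched, so the same material prints at the same
# height across photographs.

#' Relief parameters
#'
#' @param relief_height_mm Height in mm of maximum-intensity features above
#'   the top of the base slab (default 3). This is the "relief height"
#'   control a user adjusts to make tactile features more or less
#'   pronounced; 0 yields a flat slab.
#' @param base_thickness_mm Thickness in mm of the solid slab under the
#'   relief (default 2); must be positive so the solid's walls never
#'   degenerate.
#' @param invert If `TRUE`, dark image regions become tall (useful when
#'   colonies are darker than the agar). Default `FALSE`: lighter is taller.
#' @param smooth_sigma Gaussian smoothing sigma in grid-node units applied
#'   to the effective intensity before scaling; 0 (default) disables
#'   smoothing. Exists to de-noise photographs, not to reshape features.
#' @return An object of class `relief_params`.
#' @export
relief_params <- function(relief_height_mm = 3, base_thickness_mm = 2,
                          invert = FALSE, smooth_sigma = 0) {
  stopifnot_param(is_number(relief_height_mm) && relief_height_mm >= 0,
                  "relief_height_mm must be >= 0")
  stopifnot_param(is_number(base_thickness_mm) && base_thickness_mm > 0,
                  "base_thickness_mm must be > 0")
  stopifnot_param(is.logical(invert) && length(invert) == 1L && !is.na(invert),
                  "invert must be TRUE or FALSE")
  stopifnot_param(is_number(smooth_sigma) && smooth_sigma >= 0,
                  "smooth_sigma must be >= 0")
  structure(list(relief_height_mm = relief_height_mm,
                 base_thickness_mm = base_thickness_mm,
                 invert = invert, smooth_sigma = smooth_sigma),
            class = "relief_params")
}

# Separable Gaussian filter with half-sample reflect boundary; kernel
# truncated at 4 sigma. A convex combination, so bounds are preserved.
gaussian_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  smooth1d <- function(m) {  # filter along rows (down each column)
    n <- nrow(m)
    # half-sample reflect: indices ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
    idx <- seq(1L - r, n + r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    idx <- pmin(n, pmax(1L, idx))
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(smooth1d(t(smooth1d(v))))
}

new_heightmap <- function(rows, cols, dx, dy, z, mask, base, relief) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 dx = dx, dy = dy, z = z, mask = mask,
                 base_thickness_mm = base, relief_height_mm = relief),
            class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf(paste0("<heightmap> %d x %d nodes, spacing %.3f x %.3f mm, ",
                     "z in [%.3f, %.3f] mm, %d/%d nodes included\n"),
              x$rows, x$cols, x$dx, x$dy,
              min(x$z[x$mask]), max(x$z[x$mask]), sum(x$mask), length(x$mask)))
  invisible(x)
}

# Physical node coordinates. Image row 1 (top) maps to the largest y so the
# printed model, viewed from above, matches the photograph's orientation.
node_x <- function(hm) (seq_len(hm$cols) - 1) * hm$dx
node_y <- function(hm) (hm$rows - seq_len(hm$rows)) * hm$dy

#' Build a physical heightmap from an intensity grid
#'
#' Applies the optional inversion and Gaussian smoothing to the intensity,
#' then maps it linearly to height: `z = base + relief * e` with
#' `e = 1 - I` when inverted, else `I`. Node spacing is square,
#' `dx = dy = physical_width_mm / (cols - 1)`; the physical height of the
#' model follows the grid aspect ratio. Image row 1 (top) maps to the
#' largest y coordinate.
#'
#' @param grid An [intensity_grid].
#' @param params A [relief_params] object.
#' @param physical_width_mm Physical width of the model in mm (x extent).
#' @return An object of class `heightmap` with fields `rows`, `cols`, `dx`,
#'   `dy` (node spacing in mm), `z` (per-node total height in mm) and
#'   `mask` (per-node inclusion flags, all `TRUE` here).
#' @export
build_heightmap <- function(grid, params = relief_params(),
                            physical_width_mm = 90) {
  if (!inherits(grid, "intensity_grid"))
    rs_param_error("build_heightmap() expects an intensity_grid")
  if (!inherits(params, "relief_params"))
    rs_param_error("params must be created with relief_params()")
  stopifnot_param(is_number(physical_width_mm) && physical_width_mm > 0,
                  "physical_width_mm must be > 0")
  e <- if (params$invert) 1 - grid$values else grid$values
  if (params$smooth_sigma > 0) e <- gaussian_smooth(e, params$smooth_sigma)
  z <- params$base_thickness_mm + params$relief_height_mm * e
  dx <- physical_width_mm / (grid$cols - 1)
  new_heightmap(grid$rows, grid$cols, dx, dx, z,
                matrix(TRUE, grid$rows, grid$cols),
                params$base_thickness_mm, params$relief_height_mm)
}

# squared radial distance of every node from `center` (length-2, mm)
node_dist2 <- function(hm, center) {
  dxv <- node_x(hm) - center[1]
  dyv <- node_y(hm) - center[2]
  outer(dyv^2, dxv^2, `+`)
}

# TRUE iff some 2x2 node block is fully included (i.e. >= 1 emitted cell)
has_full_cell <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  if (r < 2L || c < 2L) return(FALSE)
  any(mask[-r, -c] & mask[-r, -1] & mask[-1, -c] & mask[-1, -1])
}

#' Restrict a heightmap to a disc
#'
#' Marks nodes outside the disc as excluded; excluded nodes generate no
#' geometry. Used to give plate models the circular footprint of a Petri
#' dish. A node is included iff its centre lies within `radius_mm` of
#' `center` (boundary inclusive).
#'
#' @param hm A [build_heightmap()] result.
#' @param center Disc centre `(x, y)` in mm; default the grid's physical
#'   centre.
#' @param radius_mm Disc radius in mm.
#' @return The masked `heightmap`.
#' @export
apply_circular_mask <- function(hm, center = NULL, radius_mm) {
  if (!inherits(hm, "heightmap")) rs_param_error("expected a heightmap")
  stopifnot_param(is_number(radius_mm) && radius_mm > 0,
                  "radius_mm must be > 0")
  if (is.null(center))
    center <- c((hm$cols - 1) * hm$dx / 2, (hm$rows - 1) * hm$dy / 2)
  stopifnot_param(is.numeric(center) && length(center) == 2L,
                  "center must be (x, y) in mm")
  inside <- node_dist2(hm, center) <= radius_mm^2
  hm$mask <- hm$mask & inside
  if (!has_full_cell(hm$mask))
    rs_error("mask removed all content: no 2 x 2 node block remains inside the disc",
             "reliefstl_empty_mask")
  hm
}

#' Override heights on an annulus
#'
#' Sets `z` to exactly `z_mm` on every included node whose radial distance
#' from `center` lies in `[r_inner_mm, r_outer_mm]`. Used to render the
#' raised, feelable rim of a Petri-dish model.
#'
#' @param hm A `heightmap`.
#' @param center Annulus centre `(x, y)` in mm; default the grid centre.
#' @param r_inner_mm,r_outer_mm Annulus radii, `0 <= r_inner < r_outer`.
#' @param z_mm Height in mm to assign; must be at least the base thickness
#'   so the solid remains well-formed.
#' @return The modified `heightmap`.
#' @export
override_annulus <- function(hm, center = NULL, r_inner_mm, r_outer_mm, z_mm) {
  if (!inherits(hm, "heightmap")) rs_param_error("expected a heightmap")
  stopifnot_param(is_number(r_inner_mm) && r_inner_mm >= 0,
                  "r_inner_mm must be >= 0")
  stopifnot_param(is_number(r_outer_mm) && r_inner_mm < r_outer_mm,
                  "r_inner_mm must be < r_outer_mm")
  stopifnot_param(is_number(z_mm) && z_mm >= hm$base_thickness_mm,
                  "z_mm must be >= base thickness")
  if (is.null(center))
    center <- c((hm$cols - 1) * hm$dx / 2, (hm$rows - 1) * hm$dy / 2)
  d2 <- node_dist2(hm, center)
  sel <- hm$mask & d2 >= r_inner_mm^2 & d2 <= r_outer_mm^2
  hm$z[sel] <- z_mm
  hm
}

# Rectangular analogue of override_annulus: set z on the border band of
# width `width_mm` measured from the model's physical edges. Used for the
# raised frame of slide models.
override_border <- function(hm, width_mm, z_mm) {
  stopifnot_param(is_number(width_mm) && width_mm > 0, "width_mm must be > 0")
  stopifnot_param(is_number(z_mm) && z_mm >= hm$base_thickness_mm,
                  "z_mm must be >= base thickness")
  x <- node_x(hm); y <- node_y(hm)
  ex <- pmin(x, max(x) - x); ey <- pmin(y, max(y) - y)
  edge_dist <- outer(ey, ex, pmin)
  sel <- hm$mask & edge_dist <= width_mm + 1e-9
  hm$z[sel] <- z_mm
  hm
}

# Flatten an axis-aligned rectangle of the heightmap to z_mm (reserving a
# flat margin for a braille label).
flatten_rect <- function(hm, x_range, y_range, z_mm) {
  x <- node_x(hm); y <- node_y(hm)
  sel_x <- x >= x_range[1] & x <= x_range[2]
  sel_y <- y >= y_range[1] & y <= y_range[2]
  sel <- hm$mask & outer(sel_y, sel_x, `&`)
  hm$z[sel] <- z_mm
  hm
}
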