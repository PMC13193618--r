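# End-to-end generators: circular Petri-dish models and rectangular
# microscope-slide models. Both run the same pipeline -- decode, grayscale,
# resample, heightmap, shape-specific masking/overrides, solidify, STL --
# and differ only in footprint and boundary treatment. The rim/frame is
# rendered by overriding node heights rather than unioning a second mesh,
# which keeps the solid single-component and manifold by construction.

#' Petri-dish model parameters
#'
#' @param diameter_mm Plate diameter in mm (default 90, a standard Petri
#'   dish).
#' @param rim_height_mm Height of the raised rim above the base top
#'   (default 2) so the physical dish boundary is feelable.
#' @param rim_width_mm Radial width of the rim band in mm (default 2).
#' @param relief A [relief_params] object.
#' @param resolution Maximum grid dimension in nodes (default 256); see
#'   [resample_grid()].
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(diameter_mm = 90, rim_height_mm = 2, rim_width_mm = 2,
                       relief = relief_params(), resolution = 256L) {
  stopifnot_param(is_number(diameter_mm) && diameter_mm > 0,
                  "diameter_mm must be > 0")
  stopifnot_param(is_number(rim_height_mm) && rim_height_mm >= 0,
                  "rim_height_mm must be >= 0")
  stopifnot_param(is_number(rim_width_mm) && rim_width_mm > 0,
                  "rim_width_mm must be > 0")
  stopifnot_param(diameter_mm > 2 * rim_width_mm,
                  "diameter_mm must exceed twice rim_width_mm")
  if (!inherits(relief, "relief_params"))
    rs_param_error("relief must be created with relief_params()")
  stopifnot_param(is_count(resolution) && resolution >= 2,
                  "resolution must be an integer >= 2")
  structure(list(diameter_mm = diameter_mm, rim_height_mm = rim_height_mm,
                 rim_width_mm = rim_width_mm, relief = relief,
                 resolution = as.integer(resolution)),
            class = "plate_spec")
}

#' Microscope-slide model parameters
#'
#' @param width_mm Physical model width in mm (default 75, a standard
#'   slide).
#' @param height_mm Physical model height in mm, or `NULL` (default) to
#'   derive it from the image aspect ratio. A fixed height re-grids the
#'   image to the requested aspect.
#' @param frame_height_mm Height of the raised frame above the base top
#'   (default 1.5).
#' @param frame_width_mm Width of the frame band in mm (default 2).
#' @param relief A [relief_params] object.
#' @param resolution Maximum grid dimension in nodes (default 256).
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(width_mm = 75, height_mm = NULL, frame_height_mm = 1.5,
                       frame_width_mm = 2, relief = relief_params(),
                       resolution = 256L) {
  stopifnot_param(is_number(width_mm) && width_mm > 0, "width_mm must be > 0")
  stopifnot_param(is.null(height_mm) || (is_number(height_mm) && height_mm > 0),
                  "height_mm must be > 0 or NULL")
  stopifnot_param(is_number(frame_height_mm) && frame_height_mm >= 0,
                  "frame_height_mm must be >= 0")
  stopifnot_param(is_number(frame_width_mm) && frame_width_mm > 0,
                  "frame_width_mm must be > 0")
  stopifnot_param(width_mm > 2 * frame_width_mm,
                  "width_mm must exceed twice frame_width_mm")
  if (!is.null(height_mm))
    stopifnot_param(height_mm > 2 * frame_width_mm,
                    "height_mm must exceed twice frame_width_mm")
  if (!inherits(relief, "relief_params"))
    rs_param_error("relief must be created with relief_params()")
  stopifnot_param(is_count(resolution) && resolution >= 2,
                  "resolution must be an integer >= 2")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 frame_height_mm = frame_height_mm,
                 frame_width_mm = frame_width_mm, relief = relief,
                 resolution = as.integer(resolution)),
            class = "slide_spec")
}

run_stage <- function(stage, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    if (inherits(e, "reliefstl_error"))
      rs_error(sprintf("stage '%s': %s", stage, conditionMessage(e)),
               class(e)[1])
    rs_error(sprintf("stage '%s': %s", stage, conditionMessage(e)),
             "reliefstl_stage_error")
  })
  if (verbose) {
    dims <- if (inherits(out, "intensity_grid")) sprintf(" [%d x %d]", out$rows, out$cols)
    else if (inherits(out, "heightmap")) sprintf(" [%d x %d]", out$rows, out$cols)
    else if (inherits(out, "triangle_mesh")) sprintf(" [%d facets]", nrow(out$triangles))
    else ""
    message(sprintf("reliefstl: %-12s %6.2fs%s", stage,
                    proc.time()[["elapsed"]] - t0, dims))
  }
  out
}

model_summary <- function(hm, mesh, path) {
  bb <- mesh_bbox(mesh)
  list(grid_rows = hm$rows, grid_cols = hm$cols,
       triangles = nrow(mesh$triangles), vertices = nrow(mesh$vertices),
       bbox_mm = round(as.numeric(bb[, 2] - bb[, 1]), 6),
       volume_mm3 = round(mesh_volume(mesh), 6),
       stl = path)
}

emit_summary <- function(summary) {
  cat(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA), "\n", sep = "")
}

apply_label <- function(hm, label, label_position, inset_mm) {
  if (is.character(label)) label <- braille_label(label)
  ext <- label_extent(label)
  pad <- max(label$dot_diameter_mm, 1)
  W <- (hm$cols - 1) * hm$dx; H <- (hm$rows - 1) * hm$dy
  x0 <- W / 2 - ext[1] / 2
  y_top <- if (identical(label_position, "top")) H - inset_mm - pad
  else inset_mm + pad + ext[2]
  hm <- flatten_rect(hm, c(x0 - pad, x0 + ext[1] + pad),
                     c(y_top - ext[2] - pad, y_top + pad),
                     hm$base_thickness_mm)
  dots <- text_to_dots(label, origin_mm = c(x0, y_top))
  emboss_dots(hm, dots, label)
}

#' Generate a tactile Petri-dish model from a plate photograph
#'
#' Runs the full pipeline: decode the image, convert to normalized
#' grayscale, bound the working resolution, map intensity to height over
#' the base slab (physical width = plate diameter), mask to the inscribed
#' disc, raise the rim annulus to `base + rim_height`, solidify, and write
#' an STL file. A single-line JSON summary (grid size, triangle count,
#' bounding box, volume) is printed to standard output.
#'
#' The image is assumed pre-cropped to the dish region; no automatic dish
#' detection is attempted.
#'
#' @param image_path Input PNG/JPEG/TIFF photograph.
#' @param spec A [plate_spec].
#' @param out_path Output STL path.
#' @param dialect `"binary"` or `"ascii"`.
#' @param label Optional braille label: text or a [braille_label] object,
#'   embossed on a flattened margin strip inside the rim.
#' @param label_position `"bottom"` (default) or `"top"`.
#' @param verbose Log each stage with grid size and timing (to stderr).
#' @return Invisibly, a list with `summary`, `heightmap` and `mesh`.
#' @export
generate_plate <- function(image_path, spec = plate_spec(), out_path,
                           dialect = c("binary", "ascii"), label = NULL,
                           label_position = c("bottom", "top"),
                           verbose = FALSE) {
  dialect <- match.arg(dialect)
  label_position <- match.arg(label_position)
  if (!inherits(spec, "plate_spec"))
    rs_param_error("spec must be created with plate_spec()")
  img <- run_stage("load", verbose, load_image(image_path))
  grid <- run_stage("grayscale", verbose, to_grayscale(img))
  grid <- run_stage("resample", verbose, resample_grid(grid, spec$resolution))
  hm <- run_stage("heightmap", verbose,
                  build_heightmap(grid, spec$relief, spec$diameter_mm))
  radius <- spec$diameter_mm / 2
  center <- c((hm$cols - 1) * hm$dx / 2, (hm$rows - 1) * hm$dy / 2)
  hm <- run_stage("mask", verbose,
                  apply_circular_mask(hm, center, radius))
  hm <- run_stage("rim", verbose,
                  override_annulus(hm, center, radius - spec$rim_width_mm,
                                   radius,
                                   spec$relief$base_thickness_mm + spec$rim_height_mm))
  if (!is.null(label))
    hm <- run_stage("label", verbose,
                    apply_label(hm, label, label_position,
                                inset_mm = spec$rim_width_mm +
                                  (radius - sqrt(max(radius^2 - (radius / 2)^2, 0)))))
  mesh <- run_stage("solidify", verbose, heightmap_to_solid(hm))
  run_stage("write", verbose, write_stl(mesh, out_path, dialect))
  summary <- model_summary(hm, mesh, out_path)
  emit_summary(summary)
  invisible(list(summary = summary, heightmap = hm, mesh = mesh))
}

#' Generate a tactile microscope-slide model from a micrograph
#'
#' As [generate_plate()], but with a rectangular footprint, no disc mask,
#' and a raised frame band of width `frame_width_mm` along the border set
#' to `base + frame_height`. The physical size comes from the spec; with
#' `height_mm = NULL` the height follows the image aspect ratio.
#'
#' @inheritParams generate_plate
#' @param spec A [slide_spec].
#' @return Invisibly, a list with `summary`, `heightmap` and `mesh`.
#' @export
generate_slide <- function(image_path, spec = slide_spec(), out_path,
                           dialect = c("binary", "ascii"), label = NULL,
                           label_position = c("bottom", "top"),
                           verbose = FALSE) {
  dialect <- match.arg(dialect)
  label_position <- match.arg(label_position)
  if (!inherits(spec, "slide_spec"))
    rs_param_error("spec must be created with slide_spec()")
  img <- run_stage("load", verbose, load_image(image_path))
  grid <- run_stage("grayscale", verbose, to_grayscale(img))
  grid <- run_stage("resample", verbose, resample_grid(grid, spec$resolution))
  if (!is.null(spec$height_mm)) {
    # re-grid so square node spacing reproduces the requested aspect
    target_r <- max(2L, round((spec$height_mm / spec$width_mm) * (grid$cols - 1)) + 1L)
    if (target_r != grid$rows)
      grid <- run_stage("re-aspect", verbose,
                        resample_grid_to(grid, target_r, grid$cols))
  }
  hm <- run_stage("heightmap", verbose,
                  build_heightmap(grid, spec$relief, spec$width_mm))
  hm <- run_stage("frame", verbose,
                  override_border(hm, spec$frame_width_mm,
                                  spec$relief$base_thickness_mm + spec$frame_height_mm))
  if (!is.null(label))
    hm <- run_stage("label", verbose,
                    apply_label(hm, label, label_position,
                                inset_mm = spec$frame_width_mm))
  mesh <- run_stage("solidify", verbose, heightmap_to_solid(hm))
  run_stage("write", verbose, write_stl(mesh, out_path, dialect))
  summary <- model_summary(hm, mesh, out_path)
  emit_summary(summary)
  invisible(list(summary = summary, heightmap = hm, mesh = mesh))
}
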