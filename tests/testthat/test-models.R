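test_that("all-black plate: rim dominates, interior sits at base", {
  p <- tmp_png(matrix(0L, 64, 64))
  out <- tempfile(fileext = ".stl")
  spec <- plate_spec(diameter_mm = 90, rim_height_mm = 2, rim_width_mm = 2,
                     relief = relief_params(3, 2), resolution = 64)
  res <- generate_plate(p, spec, out)
  hm <- res$heightmap
  expect_equal(max(hm$z[hm$mask]), 4)  # base + rim height
  expect_equal(min(hm$z[hm$mask]), 2)  # base
  # bounding box within diameter + node diagonal
  bb <- mesh_bbox(res$mesh)
  eps <- sqrt(hm$dx^2 + hm$dy^2)
  expect_lte(bb[1, 2] - bb[1, 1], 90 + eps)
  expect_lte(bb[2, 2] - bb[2, 1], 90 + eps)
  expect_true(validate_watertight(res$mesh)$is_watertight)
  expect_true(file.exists(out))
  expect_equal(file.size(out), 84 + 50 * res$summary$triangles)
})

test_that("white disc on black becomes a plateau at base + relief", {
  n <- 81
  ctr <- (n + 1) / 2
  img <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n)
    if ((r - ctr)^2 + (c - ctr)^2 <= (n * 0.2)^2) img[r, c] <- 255L
  spec <- plate_spec(relief = relief_params(3, 2), resolution = n)
  res <- generate_plate(tmp_png(img), spec, tempfile(fileext = ".stl"))
  hm <- res$heightmap
  # node-wise oracle: direct heightmap formula on the known image
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  inside_disc <- d2 <= (n * 0.2)^2
  expect_true(all(hm$z[inside_disc & hm$mask] == 5))
  rim_or_bg <- hm$mask & !inside_disc
  expect_true(all(hm$z[rim_or_bg] %in% c(2, 4)))
})

test_that("interior heights never exceed base + relief; rim is exact", {
  set.seed(51)
  img <- matrix(sample(0:255, 96 * 96, replace = TRUE), 96, 96)
  spec <- plate_spec(diameter_mm = 80, rim_height_mm = 2.5, rim_width_mm = 3,
                     relief = relief_params(2, 1.5), resolution = 96)
  res <- generate_plate(tmp_png(img), spec, tempfile(fileext = ".stl"))
  hm <- res$heightmap
  ctr <- c((hm$cols - 1) * hm$dx / 2, (hm$rows - 1) * hm$dy / 2)
  d <- sqrt(reliefstl:::node_dist2(hm, ctr))
  rim <- hm$mask & d >= 40 - 3 & d <= 40
  interior <- hm$mask & !rim
  expect_true(all(hm$z[rim] == 1.5 + 2.5))
  expect_true(all(hm$z[interior] <= 1.5 + 2 + 1e-12))
})

test_that("doubling the diameter doubles x/y coordinates, z unchanged", {
  set.seed(52)
  img <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  p <- tmp_png(img)
  # pure geometric scaling: all planar dimensions double (rim width too)
  s1 <- plate_spec(diameter_mm = 90, rim_width_mm = 2, resolution = 48)
  s2 <- plate_spec(diameter_mm = 180, rim_width_mm = 4, resolution = 48)
  r1 <- generate_plate(p, s1, tempfile(fileext = ".stl"))
  r2 <- generate_plate(p, s2, tempfile(fileext = ".stl"))
  expect_equal(r2$mesh$vertices[, 1:2], 2 * r1$mesh$vertices[, 1:2])
  expect_equal(r2$mesh$vertices[, 3], r1$mesh$vertices[, 3])
})

test_that("slide: linear map + frame override, physical size honored", {
  img <- matrix(128L, 40, 120)
  spec <- slide_spec(width_mm = 75, frame_height_mm = 1.5, frame_width_mm = 2,
                     relief = relief_params(2, 2), resolution = 120)
  res <- generate_slide(tmp_png(img), spec, tempfile(fileext = ".stl"))
  hm <- res$heightmap
  x <- reliefstl:::node_x(hm); y <- reliefstl:::node_y(hm)
  edge <- outer(pmin(y, max(y) - y), pmin(x, max(x) - x), pmin) <= 2 + 1e-9
  interior_z <- 2 + 2 * (128 / 255)  # oracle: the heightmap formula itself
  expect_true(all(abs(hm$z[!edge] - interior_z) < 1e-12))
  expect_true(all(hm$z[edge] == 3.5))
  bb <- mesh_bbox(res$mesh)
  expect_equal(bb[1, 2] - bb[1, 1], 75)
  expect_equal(bb[2, 2] - bb[2, 1], 75 * 39 / 119)
  expect_equal(bb[3, 2], 3.5)  # base + max(frame, relief * max intensity)
  expect_true(validate_watertight(res$mesh)$is_watertight)
})

test_that("slide with fixed height re-grids to the requested aspect", {
  set.seed(53)
  img <- matrix(sample(0:255, 60 * 90, replace = TRUE), 60, 90)
  spec <- slide_spec(width_mm = 75, height_mm = 25, resolution = 90)
  res <- generate_slide(tmp_png(img), spec, tempfile(fileext = ".stl"))
  bb <- mesh_bbox(res$mesh)
  expect_equal(bb[1, 2] - bb[1, 1], 75)
  expect_equal(bb[2, 2] - bb[2, 1], 25, tolerance = 0.02)
})

test_that("synthetic hyphae-like micrograph: interior max = base + relief * max I", {
  spec_img <- colony_field_spec(size_px = c(180, 60), n_objects = 4,
                                amplitude = 0.8, sigma_px = 3,
                                min_separation_px = 12, background = 0.05,
                                seed = 7)
  img <- make_colony_image(spec_img)
  spec <- slide_spec(width_mm = 75, frame_height_mm = 1.5,
                     relief = relief_params(2, 2), resolution = 180)
  res <- generate_slide(tmp_png(img$data), spec, tempfile(fileext = ".stl"))
  hm <- res$heightmap
  x <- reliefstl:::node_x(hm); y <- reliefstl:::node_y(hm)
  edge <- outer(pmin(y, max(y) - y), pmin(x, max(x) - x), pmin) <= 2 + 1e-9
  max_i <- max(img$data) / 255
  expect_equal(max(hm$z[!edge]), 2 + 2 * max_i)
})

test_that("stage errors name the failing stage; bad spec is a param error", {
  expect_error(generate_plate(file.path(tempdir(), "ghost.png"),
                              plate_spec(), tempfile()),
               "stage 'load'")
  expect_error(plate_spec(diameter_mm = 3, rim_width_mm = 2),
               class = "reliefstl_param_error")
  expect_error(slide_spec(width_mm = 3, frame_width_mm = 2),
               class = "reliefstl_param_error")
})

test_that("a braille label embosses onto a slide and stays printable", {
  img <- matrix(40L, 80, 200)
  spec <- slide_spec(width_mm = 75, relief = relief_params(1, 2),
                     resolution = 200)
  res <- generate_slide(tmp_png(img), spec, tempfile(fileext = ".stl"),
                        label = "AB 3")
  hm <- res$heightmap
  expect_true(any(hm$z > 2 + 1 * (40 / 255) + 0.5))  # dots rise above relief
  expect_true(validate_watertight(res$mesh)$is_watertight)
})
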