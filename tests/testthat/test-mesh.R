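test_that("a flat 2x2 heightmap solidifies to a 12-facet box", {
  g <- intensity_grid(matrix(1, 2, 2))
  hm <- build_heightmap(g, relief_params(1, 2), 10)  # z = 3 everywhere
  mesh <- heightmap_to_solid(hm)
  expect_equal(nrow(mesh$triangles), 12L)
  expect_equal(nrow(mesh$vertices), 8L)
  rep <- validate_watertight(mesh)
  expect_true(rep$is_watertight)
  expect_equal(mesh_volume(mesh), 10 * 10 * 3)
})

test_that("full-grid triangle count matches the enumeration oracle", {
  set.seed(31)
  for (dims in list(c(2, 2), c(3, 5), c(7, 4), c(16, 9))) {
    r <- dims[1]; c <- dims[2]
    g <- intensity_grid(matrix(runif(r * c), r, c))
    mesh <- heightmap_to_solid(build_heightmap(g, relief_params(2, 1), 30))
    # oracle: enumerate cells and boundary edges directly
    n_cells <- 0L; n_bedges <- 0L
    for (i in seq_len(r - 1)) for (j in seq_len(c - 1)) {
      n_cells <- n_cells + 1L
      if (i == 1) n_bedges <- n_bedges + 1L
      if (i == r - 1) n_bedges <- n_bedges + 1L
      if (j == 1) n_bedges <- n_bedges + 1L
      if (j == c - 1) n_bedges <- n_bedges + 1L
    }
    expect_equal(nrow(mesh$triangles), 4L * n_cells + 2L * n_bedges)
    expect_equal(nrow(mesh$triangles),
                 4 * (r - 1) * (c - 1) + 4 * ((r - 1) + (c - 1)))
  }
})

test_that("single-cell volume follows the fixed-diagonal prism formula", {
  # corners (A, B, C, D) = (2, 2, 2, 5); diagonal split (A,C,D) + (A,D,B)
  z <- matrix(c(2, 2, 2, 5), 2, 2)  # zA=2 zB=2 zC=2 zD=5 (column-major)
  g <- intensity_grid(matrix(0, 2, 2))
  hm <- build_heightmap(g, relief_params(0, 2), 1)
  hm$z <- z
  mesh <- heightmap_to_solid(hm)
  expected <- 0.5 * ((2 + 2 + 5) / 3 + (2 + 5 + 2) / 3)  # = 3
  expect_equal(mesh_volume(mesh), expected)
  expect_equal(mesh_volume(mesh), prism_volume_oracle(hm))
})

test_that("mesh_volume matches the prism oracle on random heightmaps", {
  for (seed in 1:25) {
    hm <- random_heightmap(seed, max_dim = 24)
    mesh <- heightmap_to_solid(hm)
    v <- mesh_volume(mesh)
    expect_equal(v, prism_volume_oracle(hm), tolerance = 1e-9)
    expect_gt(v, 0)
  }
})

test_that("volume is monotone non-decreasing in relief height", {
  set.seed(33)
  g <- intensity_grid(matrix(runif(15 * 15), 15, 15))
  vols <- vapply(c(0.5, 1, 2, 4), function(rh) {
    mesh_volume(heightmap_to_solid(build_heightmap(g, relief_params(rh, 2), 40)))
  }, 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("solids from random masked heightmaps are closed 2-manifolds", {
  for (seed in 101:140) {
    hm <- random_heightmap(seed, max_dim = 32)
    rep <- validate_watertight(heightmap_to_solid(hm))
    expect_true(rep$is_watertight)
    expect_equal(rep$euler_characteristic, 2L * rep$n_components)
  }
})

test_that("masked solid vertices stay within the disc bound", {
  set.seed(35)
  g <- intensity_grid(matrix(runif(40 * 40), 40, 40))
  hm <- build_heightmap(g, relief_params(3, 2), 90)
  ctr <- c(45, 45)
  hm <- apply_circular_mask(hm, ctr, 30)
  mesh <- heightmap_to_solid(hm)
  d <- sqrt((mesh$vertices[, 1] - ctr[1])^2 + (mesh$vertices[, 2] - ctr[2])^2)
  expect_true(all(d <= 30 + sqrt(hm$dx^2 + hm$dy^2) / 2))
})

test_that("validate_watertight pinpoints defects", {
  g <- intensity_grid(matrix(runif(6 * 6, 0.2, 0.9), 6, 6))
  mesh <- heightmap_to_solid(build_heightmap(g, relief_params(2, 1.5), 25))
  expect_true(validate_watertight(mesh)$is_watertight)

  holed <- mesh
  holed$triangles <- holed$triangles[-17, , drop = FALSE]
  rep <- validate_watertight(holed)
  expect_false(rep$is_watertight)
  expect_equal(nrow(rep$boundary_edges), 3L)

  flipped <- mesh
  flipped$triangles[9, ] <- flipped$triangles[9, c(1, 3, 2)]
  rep2 <- validate_watertight(flipped)
  expect_false(rep2$is_watertight)
  expect_gte(nrow(rep2$winding_conflicts), 1L)

  expect_error(mesh_volume(holed), class = "reliefstl_validation_error")
})

test_that("empty and pinched masks are rejected", {
  g <- intensity_grid(matrix(0.5, 4, 4))
  hm <- build_heightmap(g, relief_params(3, 2), 30)
  hm$mask[] <- FALSE
  expect_error(heightmap_to_solid(hm), class = "reliefstl_no_printable_area")

  # checkerboard cells meeting only at one node: pinched geometry
  hm2 <- build_heightmap(intensity_grid(matrix(0.5, 3, 3)), relief_params(3, 2), 20)
  hm2$mask <- matrix(c(TRUE, TRUE, FALSE,
                       TRUE, TRUE, TRUE,
                       FALSE, TRUE, TRUE), 3, 3, byrow = TRUE)
  expect_error(heightmap_to_solid(hm2), class = "reliefstl_pinched_mask")
})
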