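test_that("load_image decodes PNG with exact 8-bit samples", {
  p <- tmp_png(matrix(255L, 2, 2))
  img <- load_image(p)
  expect_s3_class(img, "raster_image")
  expect_equal(img$channels, 1L)
  expect_true(all(img$data == 255L))

  samples <- matrix(sample(0:255, 30 * 20, replace = TRUE), 20, 30)
  img <- load_image(tmp_png(samples))
  expect_identical(dim(img$data), c(20L, 30L))
  expect_true(all(img$data == samples))
})

test_that("load_image reports JPEG geometry and channels", {
  arr <- array(runif(640 * 480 * 3), dim = c(480, 640, 3))
  p <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(arr, p, quality = 0.9)
  img <- load_image(p)
  expect_equal(img$width, 640L)
  expect_equal(img$height, 480L)
  expect_equal(img$channels, 3L)
})

test_that("16-bit PNG samples are reduced by integer division by 257", {
  vals <- matrix(c(65535L, 0L, 32768L, 257L, 256L, 1000L), 2, 3, byrow = TRUE)
  img <- load_image(write_png16_gray(vals))
  expect_identical(img$data, matrix(vals %/% 257L, 2, 3, byrow = FALSE) * 1L)
  expect_equal(img$data[1, 1], 255L)
  expect_equal(img$data[2, 3], 1000L %/% 257L)
})

test_that("alpha is composited over white and dropped", {
  # fully transparent pixel becomes white; opaque pixel keeps its value
  arr <- array(0, dim = c(2, 2, 4))
  arr[, , 1:3] <- 0.2
  arr[, , 4] <- c(0, 1, 1, 1)  # pixel (1,1) transparent
  p <- tempfile(fileext = ".png")
  png::writePNG(arr, p)
  img <- load_image(p)
  expect_equal(img$channels, 3L)
  expect_true(all(img$data[1, 1, ] == 255L))
  expect_true(all(img$data[2, 1, ] == 51L))
})

test_that("baseline TIFF round-trips through the built-in codec", {
  gray <- matrix(sample(0:255, 12 * 9, replace = TRUE), 9, 12)
  p <- tempfile(fileext = ".tif")
  reliefstl:::write_tiff_baseline(gray, p)
  img <- load_image(p)
  expect_true(all(img$data == gray))

  rgb <- array(sample(0:255, 8 * 6 * 3, replace = TRUE), dim = c(6, 8, 3))
  p3 <- tempfile(fileext = ".tif")
  reliefstl:::write_tiff_baseline(rgb, p3)
  img3 <- load_image(p3)
  expect_equal(img3$channels, 3L)
  expect_true(all(img3$data == rgb))

  g16 <- matrix(c(65535L, 0L, 514L, 257L), 2, 2)
  p16 <- tempfile(fileext = ".tif")
  reliefstl:::write_tiff_baseline(g16, p16, bits = 16L)
  expect_identical(load_image(p16)$data, matrix(g16 %/% 257L, 2, 2))
})

test_that("unreadable and degenerate inputs raise the contracted errors", {
  expect_error(load_image(file.path(tempdir(), "nope.png")),
               class = "reliefstl_unsupported_image")
  junk <- tempfile(fileext = ".png")
  writeLines("this is not an image", junk)
  expect_error(load_image(junk), class = "reliefstl_unsupported_image")
  expect_error(load_image(junk), "unsupported image.*nope|not PNG|unsupported",
               ignore.case = TRUE)
  tiny <- tmp_png(matrix(7L, 1, 3))
  expect_error(load_image(tiny), class = "reliefstl_degenerate_image")
})

test_that("to_grayscale applies Rec. 601 luma to RGB and identity to gray", {
  rgb <- array(0L, dim = c(2, 2, 3))
  rgb[1, 1, ] <- c(0L, 0L, 0L)
  rgb[1, 2, ] <- c(255L, 255L, 255L)
  rgb[2, 1, ] <- c(255L, 0L, 0L)
  rgb[2, 2, ] <- c(10L, 200L, 30L)
  g <- to_grayscale(raster_image(rgb))
  expect_equal(g$values[1, 1], 0)
  expect_equal(g$values[1, 2], 1)
  expect_equal(g$values[2, 1], 0.299 * 255 / 255)  # 76.245 / 255
  expect_equal(g$values[2, 2], (0.299 * 10 + 0.587 * 200 + 0.114 * 30) / 255)

  gray <- matrix(c(0L, 128L, 200L, 255L), 2, 2)
  expect_equal(to_grayscale(raster_image(gray))$values, gray / 255)
})

test_that("grayscale is bounded by the per-pixel channel range", {
  set.seed(11)
  for (rep in 1:5) {
    rgb <- array(sample(0:255, 6 * 7 * 3, replace = TRUE), dim = c(6, 7, 3))
    g <- to_grayscale(raster_image(rgb))
    lo <- apply(rgb, c(1, 2), min) / 255
    hi <- apply(rgb, c(1, 2), max) / 255
    expect_true(all(g$values >= lo - 1e-12 & g$values <= hi + 1e-12))
  }
})

test_that("resample_grid contracts: no-op, aspect, corners, idempotence", {
  g <- intensity_grid(matrix(runif(100 * 100), 100, 100))
  expect_identical(resample_grid(g, 200), g)

  flat <- intensity_grid(matrix(0.5, 512, 256))
  out <- resample_grid(flat, 128)
  expect_equal(c(out$rows, out$cols), c(128L, 64L))
  expect_true(all(abs(out$values - 0.5) < 1e-9))

  ramp <- intensity_grid(matrix(rep(seq(0, 1, length.out = 4), each = 4), 4, 4))
  out2 <- resample_grid(ramp, 2)
  expect_equal(dim(out2$values), c(2L, 2L))
  expect_equal(out2$values[, 1], c(0, 0))
  expect_equal(out2$values[, 2], c(1, 1))

  set.seed(5)
  g3 <- intensity_grid(matrix(runif(80 * 37), 80, 37))
  once <- resample_grid(g3, 21)
  expect_identical(resample_grid(once, 21), once)
  expect_error(resample_grid(g3, 1), class = "reliefstl_param_error")
})
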