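# Shared fixture builders. Everything is generated in code at test time;
# nothing binary ships with the package.

# write an 8-bit PNG from integer samples in [0, 255]; matrix or h x w x ch
tmp_png <- function(samples, path = tempfile(fileext = ".png")) {
  png::writePNG(samples / 255, path)
  path
}

# --- minimal 16-bit grayscale PNG writer (independent of the package; the
# --- package itself never writes 16-bit) ------------------------------------

# CRC-32 (reflected, poly 0xEDB88320) on raw bytes, via double arithmetic to
# dodge R's signed 32-bit integers
crc32 <- function(bytes) {
  poly <- 0xEDB88320
  tab <- vapply(0:255, function(n) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) bitwXorDouble(floor(c / 2), poly) else floor(c / 2)
    }
    c
  }, 0)
  crc <- 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXorDouble(tab[(bitwXorDouble(crc, b) %% 256) + 1], floor(crc / 256))
  }
  bitwXorDouble(crc, 0xFFFFFFFF)
}

# 32-bit XOR on doubles holding unsigned values
bitwXorDouble <- function(a, b) {
  hi_a <- floor(a / 2^16); lo_a <- a %% 2^16
  hi_b <- floor(b / 2^16); lo_b <- b %% 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

u32be <- function(x) {
  as.raw(c(floor(x / 2^24) %% 256, floor(x / 2^16) %% 256,
           floor(x / 2^8) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

# 16-bit grayscale PNG from an integer matrix of samples in [0, 65535]
write_png16_gray <- function(samples, path = tempfile(fileext = ".png")) {
  h <- nrow(samples); w <- ncol(samples)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  scan <- unlist(lapply(seq_len(h), function(r) {
    c(as.raw(0), writeBin(as.integer(samples[r, ]), raw(), size = 2,
                          endian = "big"))
  }))
  idat <- memCompress(scan, "gzip")  # R emits a zlib stream, as PNG requires
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  path
}

# --- random heightmaps for property tests -----------------------------------

# random heightmap: random grid size in [2, max_dim], random intensities,
# optionally disc-masked (the package's mask mechanism)
random_heightmap <- function(seed, max_dim = 64, masked = NA) {
  set.seed(seed)
  r <- sample(2:max_dim, 1); c <- sample(2:max_dim, 1)
  grid <- intensity_grid(matrix(runif(r * c), r, c))
  params <- relief_params(relief_height_mm = runif(1, 0.5, 6),
                          base_thickness_mm = runif(1, 0.5, 4))
  hm <- build_heightmap(grid, params, physical_width_mm = runif(1, 20, 120))
  if (is.na(masked)) masked <- runif(1) < 0.65
  if (masked && r >= 3 && c >= 3) {
    W <- (c - 1) * hm$dx; H <- (r - 1) * hm$dy
    for (try in 1:50) {
      ctr <- c(runif(1, 0.25 * W, 0.75 * W), runif(1, 0.25 * H, 0.75 * H))
      rad <- runif(1, 0.2, 0.7) * max(W, H)
      hm2 <- tryCatch(apply_circular_mask(hm, ctr, rad),
                      reliefstl_empty_mask = function(e) NULL)
      if (!is.null(hm2)) return(hm2)
    }
  }
  hm
}

# independent volume oracle: prism decomposition over the fixed cell
# diagonal (A, C, D) + (A, D, B), area * mean corner height each
prism_volume_oracle <- function(hm) {
  m <- hm$mask; z <- hm$z
  r <- hm$rows; c <- hm$cols
  vol <- 0
  half <- hm$dx * hm$dy / 2
  for (i in seq_len(r - 1)) {
    for (j in seq_len(c - 1)) {
      if (m[i, j] && m[i, j + 1] && m[i + 1, j] && m[i + 1, j + 1]) {
        zA <- z[i, j]; zB <- z[i, j + 1]; zC <- z[i + 1, j]; zD <- z[i + 1, j + 1]
        vol <- vol + half * ((zA + zC + zD) / 3 + (zA + zD + zB) / 3)
      }
    }
  }
  vol
}

# Grade-1 braille dot counts, frozen from the Unicode braille block
# (BRAILLE PATTERN DOTS-xxx names), independent of the package table
braille_expected_counts <- c(
  A = 1, B = 2, C = 2, D = 3, E = 2, F = 3, G = 4, H = 3, I = 2, J = 3,
  K = 2, L = 3, M = 3, N = 4, O = 3, P = 4, Q = 5, R = 4, S = 3, T = 4,
  U = 3, V = 4, W = 4, X = 4, Y = 5, Z = 4)
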