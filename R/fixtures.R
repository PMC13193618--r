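# Synthetic plate-photograph and micrograph generation.
#
# Colonies are rendered as isotropic Gaussian bumps (soft edges like real
# colony photographs, not hard discs) on a uniform agar background, so
# threshold-based counting downstream exercises the relief pipeline rather
# than the generator. Object centers sit on integer pixels inside the
# inscribed dish area; the separation constraint is expressed in multiples
# of sigma so count recovery has a provable margin. Every image is fully
# determined by its seed.

#' Synthetic colony-field parameters
#'
#' @param size_px Image size in pixels, `(width, height)` or a scalar
#'   (default 256).
#' @param n_objects Number of colony-like objects (default 5).
#' @param amplitude Peak intensity of each object above background, in
#'   `(0, 1]` (default 0.85).
#' @param sigma_px Gaussian radius of each object in pixels (default 5).
#' @param min_separation_px Minimum center-to-center distance (default
#'   `8 * sigma_px`, which keeps thresholded objects disjoint).
#' @param background Background intensity in `[0, 1)` (default 0.1,
#'   emulating dark agar under bright colonies).
#' @param seed RNG seed; mandatory so every fixture is reproducible.
#' @param layout `"random"` (uniform inside the inscribed dish area),
#'   `"ring"` (evenly spaced on a circle, like colonies along a streak
#'   arc) or `"streak"` (along zigzag streak segments).
#' @return An object of class `colony_field_spec`.
#' @export
colony_field_spec <- function(size_px = 256L, n_objects = 5L,
                              amplitude = 0.85, sigma_px = 5,
                              min_separation_px = 8 * sigma_px,
                              background = 0.1, seed,
                              layout = c("random", "ring", "streak")) {
  layout <- match.arg(layout)
  if (length(size_px) == 1L) size_px <- c(size_px, size_px)
  stopifnot_param(all(vapply(size_px, is_count, TRUE)) && all(size_px >= 16),
                  "size_px must be integer(s) >= 16")
  stopifnot_param(is_count(n_objects) && n_objects >= 0,
                  "n_objects must be a non-negative integer")
  stopifnot_param(is_number(amplitude) && amplitude > 0 && amplitude <= 1,
                  "amplitude must be in (0, 1]")
  stopifnot_param(is_number(sigma_px) && sigma_px > 0, "sigma_px must be > 0")
  stopifnot_param(is_number(min_separation_px) && min_separation_px >= 0,
                  "min_separation_px must be >= 0")
  stopifnot_param(is_number(background) && background >= 0 && background < 1,
                  "background must be in [0, 1)")
  if (missing(seed) || !is_count(seed))
    rs_param_error("seed is mandatory (an integer) so fixtures are reproducible")
  structure(list(size_px = as.integer(size_px), n_objects = as.integer(n_objects),
                 amplitude = amplitude, sigma_px = sigma_px,
                 min_separation_px = min_separation_px,
                 background = background, seed = as.integer(seed),
                 layout = layout),
            class = "colony_field_spec")
}

# rejection-sample n integer-pixel centers with pairwise min separation
# inside the disc of radius `radius` around `center`; error after `limit`
# draws
sample_centers <- function(n, center, radius, min_sep, limit = 10000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  pts <- matrix(0, n, 2)
  placed <- 0L
  for (attempt in seq_len(limit)) {
    cand <- round(center + stats::runif(2, -radius, radius))
    if (sum((cand - center)^2) > radius^2) next
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
        (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
    if (placed == n) return(pts)
  }
  rs_error(sprintf(
    "could not place %d objects with %.0f px separation in %d attempts; try fewer objects",
    n, min_sep, limit), "reliefstl_packing_error")
}

# render Gaussian bumps at `centers` (x, y pixel coords, row 1 = top) onto
# a constant background; returns a raster_image
render_blobs <- function(size_px, centers, amplitude, sigma_px, background) {
  w <- size_px[1]; h <- size_px[2]
  xs <- seq_len(w); ys <- seq_len(h)
  v <- matrix(background, h, w)
  amplitude <- rep_len(amplitude, nrow(centers))
  sigma_px <- rep_len(sigma_px, nrow(centers))
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-((xs - centers[k, 1])^2) / (2 * sigma_px[k]^2))
    gy <- exp(-((ys - centers[k, 2])^2) / (2 * sigma_px[k]^2))
    v <- v + amplitude[k] * outer(gy, gx)
  }
  raster_image(matrix(as.integer(round(pmin(pmax(v, 0), 1) * 255)), h, w))
}

#' Generate a synthetic colony image with a known object count
#'
#' Renders `n_objects` Gaussian bumps over a uniform background:
#' `I = clip(background + sum_k A exp(-((x-x_k)^2 + (y-y_k)^2) / (2 sigma^2)), 0, 1) * 255`.
#' Centers are at least `min_separation_px` apart and lie inside the
#' inscribed dish area, so the objects survive circular plate masking.
#' Deterministic given the spec's seed.
#'
#' @param spec A [colony_field_spec].
#' @return A grayscale [raster_image].
#' @export
make_colony_image <- function(spec) {
  if (!inherits(spec, "colony_field_spec"))
    rs_param_error("make_colony_image() expects a colony_field_spec")
  w <- spec$size_px[1]; h <- spec$size_px[2]
  center <- c((w + 1) / 2, (h + 1) / 2)
  # keep centers clear of the rim band and mask boundary: 80% of the
  # inscribed radius, minus 3 sigma so whole bumps stay inside
  radius <- 0.8 * (min(w, h) / 2) - 3 * spec$sigma_px
  if (radius < 1) radius <- min(w, h) / 4
  with_local_seed(spec$seed, {
    centers <- switch(spec$layout,
      random = sample_centers(spec$n_objects, center, radius,
                              spec$min_separation_px),
      ring = {
        n <- spec$n_objects
        if (n == 0L) matrix(numeric(0), 0, 2)
        else {
          ang <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(1, 0, 2 * pi)
          r <- 0.75 * radius
          round(cbind(center[1] + r * cos(ang), center[2] + r * sin(ang)))
        }
      },
      streak = streak_centers(spec, center, radius)$centers)
    render_blobs(spec$size_px, centers, spec$amplitude, spec$sigma_px,
                 spec$background)
  })
}

# zigzag streak path: objects distributed over segments with strictly
# decreasing counts (successful isolation streaks get sparser)
streak_centers <- function(spec, center, radius, n_segments = 4L) {
  # segment share ~ 8:4:2:1
  weights <- 2^((n_segments - 1):0)
  counts <- pmax(1L, round(spec$n_objects * weights / sum(weights)))
  # enforce strictly decreasing counts
  for (i in 2:n_segments)
    if (counts[i] >= counts[i - 1]) counts[i] <- max(1L, counts[i - 1] - 1L)
  rel <- cbind(c(0.15, 0.85, 0.15, 0.85, 0.2),
               c(0.15, 0.3, 0.5, 0.7, 0.88))
  span <- 2 * radius
  corners <- cbind(center[1] - radius + rel[, 1] * span,
                   center[2] - radius + rel[, 2] * span)
  centers <- NULL
  for (s in seq_len(n_segments)) {
    t <- (seq_len(counts[s]) - 0.5) / counts[s]
    px <- corners[s, 1] + t * (corners[s + 1, 1] - corners[s, 1])
    py <- corners[s, 2] + t * (corners[s + 1, 2] - corners[s, 2])
    jit <- spec$sigma_px * matrix(stats::runif(2 * counts[s], -1, 1), ncol = 2)
    centers <- rbind(centers, round(cbind(px, py) + jit))
  }
  list(centers = centers, counts = counts)
}

#' Generate a synthetic streak-plate image
#'
#' `mode = "successful"` renders objects along zigzag streak segments with
#' strictly decreasing density, ending in isolated colonies; `mode =
#' "overgrown"` renders a dense confluent lawn (overlapping bumps covering
#' most of the plate) that thresholds to a single large region. Both are
#' deterministic given the spec's seed.
#'
#' @param spec A [colony_field_spec]; for `"successful"`, `n_objects` is
#'   the total across segments.
#' @param mode `"successful"` or `"overgrown"`.
#' @return A grayscale [raster_image].
#' @export
make_streak_image <- function(spec, mode = c("successful", "overgrown")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "colony_field_spec"))
    rs_param_error("make_streak_image() expects a colony_field_spec")
  w <- spec$size_px[1]; h <- spec$size_px[2]
  center <- c((w + 1) / 2, (h + 1) / 2)
  radius <- 0.8 * (min(w, h) / 2) - 3 * spec$sigma_px
  with_local_seed(spec$seed, {
    if (mode == "successful") {
      centers <- streak_centers(spec, center, radius)$centers
    } else {
      # confluent lawn: bump lattice at 1.5 sigma spacing (midpoints stay
      # above half peak, so the thresholded lawn is one connected region).
      # Overgrowth spans essentially the whole dish, not just the streak
      # zone, so the lawn disc is nearly the full inscribed circle.
      radius <- 0.95 * (min(w, h) / 2) - spec$sigma_px
      step <- 1.5 * spec$sigma_px
      gx <- seq(center[1] - radius, center[1] + radius, by = step)
      gy <- seq(center[2] - radius, center[2] + radius, by = step)
      lat <- expand.grid(x = gx, y = gy)
      keep <- (lat$x - center[1])^2 + (lat$y - center[2])^2 <= radius^2
      lat <- lat[keep, ]
      jit <- 0.3 * spec$sigma_px * matrix(stats::runif(2 * nrow(lat), -1, 1),
                                          ncol = 2)
      centers <- round(as.matrix(lat) + jit)
    }
    render_blobs(spec$size_px, centers, spec$amplitude, spec$sigma_px,
                 spec$background)
  })
}

#' Label connected regions of a logical matrix
#'
#' Two-pass run-based labeling with 4-connectivity. Used to count
#' thresholded colonies both on images and on heightmaps.
#'
#' @param mask A logical matrix.
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `n` (number of regions).
#' @export
label_regions <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    rs_param_error("label_regions() expects a logical matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  env <- new.env()
  env$parent <- integer(0)
  uf_find <- function(i) {
    p <- env$parent
    root <- i
    while (p[root] != root) root <- p[root]
    while (p[i] != root) { nxt <- p[i]; p[i] <- root; i <- nxt }
    env$parent <- p
    root
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra != rb) env$parent[max(ra, rb)] <- min(ra, rb)
  }
  uf_new <- function() {
    env$parent <- c(env$parent, length(env$parent) + 1L)
    length(env$parent)
  }
  prev_runs <- NULL  # matrix: from, to, label (runs of the previous row)
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs <- cbind(from = starts[keep], to = ends[keep], label = 0L)
    for (i in seq_len(nrow(runs))) {
      lbl <- 0L
      if (!is.null(prev_runs)) {
        overlap <- which(prev_runs[, "to"] >= runs[i, "from"] &
                           prev_runs[, "from"] <= runs[i, "to"])
        for (j in overlap) {
          pl <- prev_runs[j, "label"]
          if (lbl == 0L) lbl <- pl else uf_union(lbl, pl)
        }
      }
      if (lbl == 0L) lbl <- uf_new()
      runs[i, "label"] <- lbl
      labels[r, runs[i, "from"]:runs[i, "to"]] <- lbl
    }
    prev_runs <- runs
  }
  n_labels <- length(env$parent)
  if (n_labels == 0L) return(list(labels = labels, n = 0L))
  roots <- vapply(seq_len(n_labels), uf_find, 0L)
  compact <- match(roots, sort(unique(roots)))
  pos <- labels > 0L
  labels[pos] <- compact[labels[pos]]
  list(labels = labels, n = length(unique(compact)))
}

#' Count raised regions of a heightmap
#'
#' Thresholds included nodes at `z > z_threshold_mm` and counts
#' 4-connected regions — the end-to-end check behind teaching models with
#' a defined number of cells: k generated colonies should come back as k
#' touchable bumps.
#'
#' @param hm A `heightmap`.
#' @param z_threshold_mm Height threshold in mm; the conventional choice is
#'   `base + relief / 2` (default).
#' @return Number of raised regions (integer).
#' @export
count_raised_regions <- function(hm,
                                 z_threshold_mm = hm$base_thickness_mm +
                                   hm$relief_height_mm / 2) {
  if (!inherits(hm, "heightmap")) rs_param_error("expected a heightmap")
  label_regions(hm$mask & hm$z > z_threshold_mm)$n
}
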