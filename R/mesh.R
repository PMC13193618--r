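# Heightmap solidification and mesh validation.
#
# The solid is assembled from the grid: a relief top, a flat bottom at
# z = 0, and vertical walls wherever an emitted cell borders an unemitted
# region or the grid edge. A cell is emitted iff all four of its corner
# nodes are included. With a positive base thickness every wall has
# positive height, so no degenerate facet can be produced, and the fixed
# cell-diagonal split makes output byte-reproducible.

new_triangle_mesh <- function(vertices, triangles) {
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<triangle_mesh> %d vertices, %d facets, bbox %.1f x %.1f x %.1f mm\n",
              nrow(x$vertices), nrow(x$triangles),
              bb[1, 2] - bb[1, 1], bb[2, 2] - bb[2, 1], bb[3, 2] - bb[3, 1]))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh A `triangle_mesh`.
#' @return A 3 x 2 matrix; rows x/y/z, columns min/max (mm).
#' @export
mesh_bbox <- function(mesh) {
  matrix(c(range(mesh$vertices[, 1]),
           range(mesh$vertices[, 2]),
           range(mesh$vertices[, 3])), nrow = 3, byrow = TRUE)
}

# Unit outward facet normals, recomputed from winding (right-hand rule).
facet_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

facet_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Solidify a heightmap into a watertight triangle mesh
#'
#' Emits a grid cell iff all four corner nodes are included. The top
#' surface splits each cell into two triangles along the fixed
#' (low-row, low-col) to (high-row, high-col) diagonal at the node heights;
#' the bottom repeats the cells at z = 0 with downward winding; every cell
#' edge adjacent to an unemitted region or the grid border becomes a
#' vertical wall quad. Vertices are deduplicated by grid-node index.
#' The mask boundary is therefore a staircase of axis-aligned walls; at the
#' default resolution the stair size is sub-node (< 0.5 mm on a 90 mm
#' plate).
#'
#' Masks in this package come from disc masking, which cannot produce two
#' emitted cells meeting only at a corner; if a hand-crafted mask does, the
#' geometry would be pinched (non-manifold) and is rejected.
#'
#' @param hm A [build_heightmap()] result (optionally masked).
#' @return A `triangle_mesh` with fields `vertices` (n x 3 mm) and
#'   `triangles` (m x 3 vertex indices, counter-clockwise from outside).
#' @export
heightmap_to_solid <- function(hm) {
  if (!inherits(hm, "heightmap")) rs_param_error("expected a heightmap")
  m <- hm$mask
  rows <- hm$rows; cols <- hm$cols
  cellin <- m[-rows, -cols, drop = FALSE] & m[-rows, -1, drop = FALSE] &
    m[-1, -cols, drop = FALSE] & m[-1, -1, drop = FALSE]
  if (!any(cellin))
    rs_error("no printable area: no fully included 2 x 2 node block",
             "reliefstl_no_printable_area")
  cr <- nrow(cellin); cc <- ncol(cellin)
  if (cr > 1L && cc > 1L) {
    a <- cellin[-cr, -cc, drop = FALSE]; b <- cellin[-1, -1, drop = FALSE]
    cpat <- cellin[-cr, -1, drop = FALSE]; dpat <- cellin[-1, -cc, drop = FALSE]
    if (any((a & b & !cpat & !dpat) | (cpat & dpat & !a & !b)))
      rs_error("mask produces pinched (corner-touching) cells; not manifold",
               "reliefstl_pinched_mask")
  }
  pad <- function(x, top, bottom, left, right) {
    out <- matrix(FALSE, cr + top + bottom, cc + left + right)
    out[top + seq_len(cr), left + seq_len(cc)] <- x
    out
  }
  # node is used iff it is a corner of some emitted cell
  used <- pad(cellin, 0, 1, 0, 1) | pad(cellin, 0, 1, 1, 0) |
    pad(cellin, 1, 0, 0, 1) | pad(cellin, 1, 0, 1, 0)
  n_used <- sum(used)
  topidx <- matrix(NA_integer_, rows, cols)
  topidx[used] <- seq_len(n_used)
  botidx <- topidx + n_used

  xs <- node_x(hm); ys <- node_y(hm)
  nodes <- which(used, arr.ind = TRUE)
  ord <- order(topidx[used])  # which() is column-major, same order as indices
  nodes <- nodes[ord, , drop = FALSE]
  vx <- xs[nodes[, 2]]; vy <- ys[nodes[, 1]]; vz <- hm$z[nodes]
  vertices <- rbind(cbind(vx, vy, vz), cbind(vx, vy, 0))
  dimnames(vertices) <- NULL

  cells <- which(cellin, arr.ind = TRUE)
  r <- cells[, 1]; c <- cells[, 2]
  A <- topidx[cbind(r, c)];     B <- topidx[cbind(r, c + 1L)]
  C <- topidx[cbind(r + 1L, c)]; D <- topidx[cbind(r + 1L, c + 1L)]
  top_tris <- rbind(cbind(A, C, D), cbind(A, D, B))
  bot_tris <- rbind(cbind(A, D, C), cbind(A, B, D)) + n_used

  # wall edges: for each (P, Q) top pair, quad (P, Q, Qb), (P, Qb, Pb);
  # P -> Q is chosen so its 90-degree CCW rotation points out of the solid.
  no_neighbor <- function(dr, dc) {
    nb <- matrix(FALSE, cr, cc)
    rs <- seq_len(cr) + dr; cs <- seq_len(cc) + dc
    okr <- rs >= 1L & rs <= cr; okc <- cs >= 1L & cs <= cc
    nb[okr, okc] <- cellin[rs[okr], cs[okc]]
    cellin & !nb
  }
  wall_pq <- function(sel, p_off, q_off) {
    w <- which(sel, arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    P <- topidx[cbind(w[, 1] + p_off[1], w[, 2] + p_off[2])]
    Q <- topidx[cbind(w[, 1] + q_off[1], w[, 2] + q_off[2])]
    rbind(cbind(P, Q, Q + n_used), cbind(P, Q + n_used, P + n_used))
  }
  walls <- rbind(
    wall_pq(no_neighbor(-1L, 0L), c(0L, 0L), c(0L, 1L)),   # north (+y out)
    wall_pq(no_neighbor(1L, 0L),  c(1L, 1L), c(1L, 0L)),   # south (-y out)
    wall_pq(no_neighbor(0L, -1L), c(1L, 0L), c(0L, 0L)),   # west  (-x out)
    wall_pq(no_neighbor(0L, 1L),  c(0L, 1L), c(1L, 1L)))   # east  (+x out)

  triangles <- rbind(top_tris, bot_tris, walls)
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"
  new_triangle_mesh(vertices, triangles)
}

#' Signed volume of a watertight mesh
#'
#' Sums the signed tetrahedra (origin, v0, v1, v2) over all facets,
#' `sum(det) / 6`; positive for a closed, outward-oriented surface.
#'
#' @param mesh A `triangle_mesh` that passes [validate_watertight()].
#' @return Volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  rep_ok <- validate_watertight(mesh)
  if (!rep_ok$is_watertight)
    rs_validation_error(paste0("mesh_volume() requires a watertight mesh: ",
                               format_report(rep_ok)))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  d <- v[tr[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
    a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
    a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  sum(det) / 6
}

format_report <- function(rep) {
  sprintf("%d boundary edge(s), %d over-shared edge(s), %d winding conflict(s), %d degenerate facet(s)",
          nrow(rep$boundary_edges), nrow(rep$overshared_edges),
          nrow(rep$winding_conflicts), length(rep$degenerate_facets))
}

#' Validate that a mesh is a printable closed 2-manifold
#'
#' Reports edges bordered by a facet count other than 2, pairs of facets
#' traversing an edge in the same direction (inconsistent winding),
#' zero-area facets, the number of connected components, and the Euler
#' characteristic V - E + F (2 per closed genus-0 component). An empty
#' report (`is_watertight = TRUE`) means the mesh is printable.
#'
#' @param mesh A `triangle_mesh`.
#' @return An object of class `watertight_report`.
#' @export
validate_watertight <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) rs_param_error("expected a triangle_mesh")
  tr <- mesh$triangles
  nv <- nrow(mesh$vertices)
  if (any(tr < 1L) || any(tr > nv))
    rs_validation_error("triangle indices out of range")
  ea <- c(tr[, 1], tr[, 2], tr[, 3])
  eb <- c(tr[, 2], tr[, 3], tr[, 1])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  ukey <- (lo - 1) * as.double(nv) + hi      # undirected edge key
  dkey <- (ea - 1) * as.double(nv) + eb      # directed edge key
  us <- sort(ukey)
  runs <- rle(us)
  n_edges <- length(runs$lengths)
  bad_u <- runs$values[runs$lengths != 2L]
  over_u <- runs$values[runs$lengths > 2L]
  bound_u <- runs$values[runs$lengths == 1L]
  # a directed edge appearing twice means two facets wind the same way
  dup_d <- unique(dkey[duplicated(dkey)])
  unkey <- function(k) {
    if (length(k) == 0L) return(matrix(integer(0), 0, 2))
    cbind(as.integer((k - 1) %/% nv) + 1L, as.integer((k - 1) %% nv) + 1L)
  }
  degen <- which(facet_areas(mesh) <= 0)

  g <- igraph::graph_from_edgelist(unkey(runs$values), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  n_comp <- comp$no
  euler <- nv - n_edges + nrow(tr)
  ok <- length(bad_u) == 0L && length(dup_d) == 0L && length(degen) == 0L &&
    euler == 2L * n_comp
  structure(list(
    boundary_edges = unkey(bound_u),
    overshared_edges = unkey(over_u),
    winding_conflicts = unkey(dup_d),
    degenerate_facets = degen,
    n_vertices = nv, n_edges = n_edges, n_facets = nrow(tr),
    n_components = n_comp, euler_characteristic = euler,
    is_watertight = ok), class = "watertight_report")
}

#' @export
print.watertight_report <- function(x, ...) {
  cat(sprintf("<watertight_report> V=%d E=%d F=%d, chi=%d, components=%d\n",
              x$n_vertices, x$n_edges, x$n_facets, x$euler_characteristic,
              x$n_components))
  cat(if (x$is_watertight) "  closed 2-manifold: printable\n"
      else paste0("  NOT watertight: ", format_report(x), "\n"))
  invisible(x)
}
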