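# Binary and ASCII STL serialization.
#
# Binary layout (de-facto 3D Systems spec): 80-byte header, uint32-LE facet
# count, then 50 bytes per facet (12 float32-LE: normal, v0, v1, v2; plus a
# 2-byte attribute count, always 0). File size is exactly 84 + 50 n.
# STL is unitless; this package writes 1 STL unit = 1 mm, the slicer-world
# convention. Facet normals are recomputed from vertex winding at write
# time rather than trusted from upstream: most slicers ignore stored
# normals, so consistency with winding matters more than provenance.

stl_header_text <- function() {
  sprintf("reliefstl %s binary STL (units: mm)",
          as.character(utils::packageVersion("reliefstl")))
}

#' Write a mesh to an STL file
#'
#' Refuses meshes that fail [validate_watertight()] (slicers require a
#' closed 2-manifold). The binary dialect is the default; ASCII is kept for
#' human inspection and tests. Facets are written in mesh order, so
#' identical meshes produce byte-identical files.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  rep <- validate_watertight(mesh)
  if (!rep$is_watertight)
    rs_validation_error(paste0("refusing to write non-manifold mesh: ",
                               format_report(rep)))
  tr <- mesh$triangles
  n <- nrow(tr)
  # quantize vertices to float32 before computing normals, so a file read
  # back and re-written is byte-identical (normals depend only on the
  # float32 coordinates that actually land in the file)
  v <- mesh$vertices
  v[] <- readBin(writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
                 "numeric", n = length(v), size = 4L, endian = "little")
  nrm <- facet_normals(new_triangle_mesh(v, tr))
  # 12 floats per facet, facet-major: normal, v1, v2, v3
  fl <- t(cbind(nrm, v[tr[, 1], , drop = FALSE], v[tr[, 2], , drop = FALSE],
                v[tr[, 3], , drop = FALSE]))
  if (dialect == "binary") {
    header <- charToRaw(stl_header_text())
    header <- c(header, raw(80L - length(header)))
    fbytes <- writeBin(as.numeric(fl), raw(), size = 4L, endian = "little")
    body <- raw(50L * n)
    body[rep((seq_len(n) - 1L) * 50L, each = 48L) + seq_len(48L)] <- fbytes
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(header, con)
    writeBin(n, con, size = 4L, endian = "little")
    writeBin(body, con)
  } else {
    num <- function(x) sprintf("%.5e", x)  # 6 significant digits
    f <- matrix(fl, nrow = 12L)
    lines <- c(
      "solid reliefstl",
      as.vector(rbind(
        sprintf("  facet normal %s %s %s", num(f[1, ]), num(f[2, ]), num(f[3, ])),
        "    outer loop",
        sprintf("      vertex %s %s %s", num(f[4, ]), num(f[5, ]), num(f[6, ])),
        sprintf("      vertex %s %s %s", num(f[7, ]), num(f[8, ]), num(f[9, ])),
        sprintf("      vertex %s %s %s", num(f[10, ]), num(f[11, ]), num(f[12, ])),
        "    endloop",
        "  endfacet")),
      "endsolid reliefstl")
    con <- file(path, "wb")  # binary mode: LF line endings on every OS
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

new_stl_document <- function(header_text, normals, v1, v2, v3) {
  structure(list(header_text = header_text, n_facets = nrow(normals),
                 normals = normals, v1 = v1, v2 = v2, v3 = v3),
            class = "stl_document")
}

#' @export
print.stl_document <- function(x, ...) {
  cat(sprintf("<stl_document> %d facets; header: %s\n", x$n_facets,
              substr(trimws(x$header_text), 1, 50)))
  invisible(x)
}

#' Read an STL file
#'
#' Auto-detects the dialect: a file is binary iff its size equals
#' 84 + 50 n for the facet count n it declares; otherwise it is parsed as
#' ASCII. Facets are returned in file order.
#'
#' @param path Path to an STL file.
#' @return An `stl_document` with `header_text`, `n_facets` and facet
#'   matrices `normals`, `v1`, `v2`, `v3` (n x 3 each).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) rs_io_error(sprintf("STL file not found: '%s'", path))
  size <- file.size(path)
  if (size >= 84) {
    con <- file(path, "rb")
    header <- readBin(con, "raw", n = 80L)
    n <- readBin(con, "integer", size = 4L, endian = "little")
    close(con)
    declared_binary <- !identical(tolower(rawToChar(header[1:5])), "solid")
    if (size == 84 + 50 * as.double(n)) {
      return(read_stl_binary(path, header, n))
    }
    if (declared_binary)
      rs_io_error(sprintf(
        "corrupt STL: '%s' declares %d facets (expected %.0f bytes) but has %.0f",
        path, n, 84 + 50 * as.double(n), as.double(size)))
  }
  read_stl_ascii(path)
}

read_stl_binary <- function(path, header, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 84)
  body <- readBin(con, "raw", n = 50L * n)
  fidx <- rep((seq_len(n) - 1L) * 50L, each = 48L) + seq_len(48L)
  fl <- readBin(body[fidx], "numeric", n = 12L * n, size = 4L,
                endian = "little")
  f <- matrix(fl, nrow = 12L)
  hdr <- rawToChar(header[header != as.raw(0)])
  new_stl_document(hdr, t(f[1:3, , drop = FALSE]), t(f[4:6, , drop = FALSE]),
                   t(f[7:9, , drop = FALSE]), t(f[10:12, , drop = FALSE]))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  if (length(trimmed) == 0L || !startsWith(trimmed[1], "solid"))
    rs_io_error(sprintf("corrupt STL: '%s' line 1: expected 'solid <name>'", path))
  parse3 <- function(i, keyword) {
    parts <- strsplit(trimmed[i], "[[:space:]]+")[[1]]
    if (length(parts) != length(keyword) + 3L ||
        !identical(parts[seq_along(keyword)], keyword))
      rs_io_error(sprintf("corrupt STL: '%s' line %d: expected '%s x y z'",
                          path, i, paste(keyword, collapse = " ")))
    vals <- suppressWarnings(as.numeric(parts[length(keyword) + 1:3]))
    if (anyNA(vals))
      rs_io_error(sprintf("corrupt STL: '%s' line %d: non-numeric coordinate",
                          path, i))
    vals
  }
  fi <- which(startsWith(trimmed, "facet normal"))
  n <- length(fi)
  normals <- matrix(0, n, 3); v1 <- matrix(0, n, 3)
  v2 <- matrix(0, n, 3); v3 <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    i <- fi[k]
    if (i + 6L > length(trimmed) || trimmed[i + 1L] != "outer loop" ||
        trimmed[i + 5L] != "endloop" || trimmed[i + 6L] != "endfacet")
      rs_io_error(sprintf("corrupt STL: '%s' line %d: malformed facet block",
                          path, i))
    normals[k, ] <- parse3(i, c("facet", "normal"))
    v1[k, ] <- parse3(i + 2L, "vertex")
    v2[k, ] <- parse3(i + 3L, "vertex")
    v3[k, ] <- parse3(i + 4L, "vertex")
  }
  name <- sub("^solid[[:space:]]*", "", trimmed[1])
  new_stl_document(name, normals, v1, v2, v3)
}

#' Rebuild a triangle mesh from an STL document
#'
#' Reconstructs indexed geometry by exact positional matching of the facet
#' corners (used by tests to round-trip generated files).
#'
#' @param doc An `stl_document`.
#' @return A `triangle_mesh`.
#' @export
stl_to_mesh <- function(doc) {
  pts <- rbind(doc$v1, doc$v2, doc$v3)
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "/")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  n <- doc$n_facets
  new_triangle_mesh(pts[uk, , drop = FALSE],
                    cbind(idx[seq_len(n)], idx[n + seq_len(n)],
                          idx[2L * n + seq_len(n)]))
}
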