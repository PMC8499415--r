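#' Triangle mesh container
#'
#' Millimetre-scale surface geometry, typically a dental arch read from STL.
#' Vertices are an `n x 3` numeric matrix, faces an `m x 3` integer matrix of
#' 1-based vertex indices.
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one vertex-index triple per row.
#' @return object of class `dental_mesh`.
#' @export
dental_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("empty mesh: no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("degenerate face with repeated vertex indices")
  structure(list(vertices = vertices, faces = faces), class = "dental_mesh")
}

#' @export
print.dental_mesh <- function(x, ...) {
  cat(sprintf("<dental_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Merge vertices closer than `tol` (mm) by grid hashing on rounded coords.
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(map[faces], ncol = 3L)
  keep <- !(new_f[, 1] == new_f[, 2] | new_f[, 2] == new_f[, 3] |
              new_f[, 1] == new_f[, 3])
  list(vertices = new_v, faces = new_f[keep, , drop = FALSE])
}

#' Read a triangle mesh from an STL file
#'
#' Handles both the binary and the ASCII STL dialect; the dialect is detected
#' from the file content, not the name. Coordinates are taken verbatim as
#' millimetres. Duplicate vertices within `tol` are merged so shared edges are
#' topologically connected.
#'
#' @param path path to an STL file.
#' @param tol vertex merge tolerance in mm (default `1e-6`).
#' @return a [dental_mesh()].
#' @export
read_mesh <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("unreadable or truncated STL file: ", path)
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[seq_len(min(80, sz))])) &&
    !any(head_raw == as.raw(0)) &&
    grepl("facet", rawToChar(head_raw), fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  if (nrow(tri) == 0L) stop("empty mesh: STL file contains no facets")
  nf <- nrow(tri) / 3L
  m <- merge_vertices(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE),
                      tol = tol)
  if (nrow(m$faces) == 0L) stop("empty mesh: all facets degenerate")
  dental_mesh(m$vertices, m$faces)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L) stop("unreadable STL file: bad facet count")
  expected <- 84 + 50 * as.numeric(nf)
  if (sz < expected) stop("truncated binary STL: ", path)
  out <- matrix(NA_real_, nrow = 3L * nf, ncol = 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    out[(3L * i - 2L):(3L * i), ] <-
      matrix(vals[4:12], ncol = 3L, byrow = TRUE)
  }
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("truncated ASCII STL: vertex count not a multiple of 3")
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- vapply(toks, length, 1L) != 4L
  if (any(bad)) stop("malformed ASCII STL vertex line")
  vals <- vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))
  if (anyNA(vals)) stop("malformed ASCII STL: non-numeric coordinate")
  t(vals)
}

#' Write a mesh as STL (binary or ASCII)
#'
#' @param mesh a [dental_mesh()].
#' @param path output path.
#' @param binary write the binary dialect (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- tri_normal(tri)
      writeBin(as.numeric(c(n, t(tri))), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines("solid gingrec", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- tri_normal(tri)
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid gingrec", con)
  }
  invisible(path)
}

tri_normal <- function(tri) {
  u <- tri[2, ] - tri[1, ]; w <- tri[3, ] - tri[1, ]
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  len <- sqrt(sum(n^2))
  if (len < 1e-30) c(0, 0, 1) else n / len
}

#' Per-tooth local coordinate frame
#'
#' Right-handed orthonormal frame: the tooth long axis is the z-axis, the
#' mesio-distal direction the x-axis, so the y-axis points bucco-orally.
#'
#' @param origin 3-vector, frame origin (mm) in world coordinates.
#' @param x_axis,y_axis,z_axis unit 3-vectors; `y_axis` defaults to
#'   `z_axis x x_axis` so only two axes need stating.
#' @return object of class `local_frame`.
#' @export
local_frame <- function(origin = c(0, 0, 0),
                        x_axis = c(1, 0, 0),
                        z_axis = c(0, 0, 1),
                        y_axis = NULL) {
  if (is.null(y_axis))
    y_axis <- c(z_axis[2] * x_axis[3] - z_axis[3] * x_axis[2],
                z_axis[3] * x_axis[1] - z_axis[1] * x_axis[3],
                z_axis[1] * x_axis[2] - z_axis[2] * x_axis[1])
  fr <- structure(list(origin = as.numeric(origin),
                       x_axis = as.numeric(x_axis),
                       y_axis = as.numeric(y_axis),
                       z_axis = as.numeric(z_axis)),
                  class = "local_frame")
  validate_frame(fr)
  fr
}

validate_frame <- function(frame, tol = 1e-9) {
  ax <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (any(abs(rowSums(ax^2) - 1) > tol))
    stop("frame axes must be unit length")
  g <- ax %*% t(ax)
  if (any(abs(g - diag(3)) > tol))
    stop("frame axes must be pairwise orthogonal")
  if (det(ax) < 0) stop("frame must be right-handed")
  invisible(TRUE)
}

#' Express a mesh in a local frame
#'
#' Applies the rigid transform taking world coordinates into the frame
#' (origin subtracted, then projected onto the axes). Distances are preserved.
#'
#' @param mesh a [dental_mesh()].
#' @param frame a [local_frame()].
#' @return transformed [dental_mesh()].
#' @export
apply_frame <- function(mesh, frame) {
  validate_frame(frame)
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  v <- sweep(mesh$vertices, 2L, frame$origin) %*% t(R)
  dental_mesh(v, mesh$faces)
}

#' Refine a mesh by longest-edge midpoint subdivision
#'
#' Repeatedly bisects each triangle at the midpoint of its longest edge until
#' every edge is at most `min_edge` long or `max_passes` passes have run. New
#' vertices lie exactly on the old surface, so geometry (and total area) is
#' unchanged; only sampling density increases. Mirrors a mesh-refinement
#' preprocessing step with a minimal-edge-length setting; optional in this
#' pipeline because spline resampling fixes the sampling density downstream.
#'
#' @param mesh a [dental_mesh()].
#' @param min_edge target maximal edge length (mm), > 0.
#' @param max_passes safety cap on subdivision sweeps (default 10).
#' @return refined [dental_mesh()].
#' @export
refine_mesh <- function(mesh, min_edge, max_passes = 10L) {
  if (!is.numeric(min_edge) || length(min_edge) != 1L || min_edge <= 0)
    stop("min_edge must be a positive length in mm")
  v <- mesh$vertices; f <- mesh$faces
  for (pass in seq_len(max_passes)) {
    p1 <- v[f[, 1], , drop = FALSE]
    p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    e <- cbind(rowSums((p1 - p2)^2), rowSums((p2 - p3)^2),
               rowSums((p3 - p1)^2))
    longest <- max.col(e, ties.method = "first")
    needs <- sqrt(e[cbind(seq_len(nrow(f)), longest)]) > min_edge
    if (!any(needs)) break
    # midpoint vertices shared through an edge key so adjacent splits reuse
    edge_a <- cbind(f[, 1], f[, 2], f[, 3])[cbind(seq_len(nrow(f)), longest)]
    edge_b <- cbind(f[, 2], f[, 3], f[, 1])[cbind(seq_len(nrow(f)), longest)]
    lo <- pmin(edge_a, edge_b); hi <- pmax(edge_a, edge_b)
    key <- paste(lo, hi)
    idx <- which(needs)
    ukey <- unique(key[idx])
    mid_of <- setNames(nrow(v) + seq_along(ukey), ukey)
    mids <- (v[as.integer(sub(" .*", "", ukey)), , drop = FALSE] +
               v[as.integer(sub(".* ", "", ukey)), , drop = FALSE]) / 2
    v <- rbind(v, mids)
    keep_f <- f[!needs, , drop = FALSE]
    new_f <- matrix(0L, nrow = 2L * length(idx), ncol = 3L)
    for (j in seq_along(idx)) {
      i <- idx[j]
      m <- mid_of[[key[i]]]
      abc <- f[i, ]
      # rotate so the split edge is (a, b)
      rot <- switch(longest[i], c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
      a <- abc[rot[1]]; b <- abc[rot[2]]; cc <- abc[rot[3]]
      new_f[2L * j - 1L, ] <- c(a, m, cc)
      new_f[2L * j, ] <- c(m, b, cc)
    }
    f <- rbind(keep_f, new_f)
  }
  dental_mesh(v, f)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (mm^2); used to verify that refinement leaves the
#' surface geometry unchanged.
#'
#' @param mesh a [dental_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - p1
  w <- v[f[, 3], , drop = FALSE] - p1
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}
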