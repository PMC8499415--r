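#' Planar cross-section polyline
#'
#' An ordered chain of in-plane points from a bucco-oral slice through a tooth
#' in its local frame. Columns of `points` are y (bucco-oral, mm) and z
#' (corono-apical, mm); ordering is coronal to apical (z of the first point is
#' not below z of the last).
#'
#' @param points numeric matrix with columns y, z (mm), at least 3 rows.
#' @param plane list with `origin` (3-vector) and `normal` (unit 3-vector) in
#'   the local frame.
#' @param site_id text label for the measuring site.
#' @param closed was the raw section a closed loop before restriction.
#' @return object of class `cross_section`.
#' @export
cross_section <- function(points, plane = list(origin = c(0, 0, 0),
                                               normal = c(1, 0, 0)),
                          site_id = "site", closed = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 2L) stop("points must have 2 columns (y, z)")
  if (nrow(points) < 3L) stop("degenerate section: fewer than 3 points")
  gaps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  if (any(gaps <= 1e-9))
    stop("degenerate section: consecutive duplicate points")
  if (points[1, 2] < points[nrow(points), 2])
    stop("section must be ordered coronal to apical (z decreasing)")
  structure(list(points = points, plane = plane, site_id = site_id,
                 closed = closed),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> site '%s': %d points, z %.3f .. %.3f mm%s\n",
              x$site_id, nrow(x$points), x$points[1, 2],
              x$points[nrow(x$points), 2],
              if (isTRUE(x$closed)) " (from closed loop)" else ""))
  invisible(x)
}

#' Extract a bucco-oral cross-section polyline from a mesh
#'
#' Slices the mesh (already expressed in the tooth's local frame) with the
#' plane `x = plane_x_offset`, whose normal is the mesio-distal x-axis so the
#' section contains the tooth long axis. Intersection segments are chained
#' into polylines; of several chains the one with the greatest z-extent is
#' kept. A closed loop is cut at its extreme-z points and the sub-chain with
#' the larger mean y (the buccal side, by frame convention) is retained.
#' Points are ordered coronal to apical.
#'
#' @param mesh a [dental_mesh()] in local-frame coordinates.
#' @param plane_x_offset mesio-distal offset of the slicing plane (mm);
#'   0 is the central site.
#' @param site_id label carried into the result.
#' @param buccal_side keep the buccal sub-chain of a closed loop
#'   (default TRUE); set FALSE to keep the full loop opened at the coronal
#'   extreme.
#' @param tol chaining tolerance in mm.
#' @return a [cross_section()].
#' @export
extract_cross_section <- function(mesh, plane_x_offset = 0,
                                  site_id = "site", buccal_side = TRUE,
                                  tol = 1e-6) {
  segs <- plane_triangle_segments(mesh, plane_x_offset, tol)
  if (is.null(segs) || nrow(segs) == 0L)
    stop("no intersection: slicing plane misses the mesh")
  chains <- chain_segments(segs, tol)
  if (length(chains) == 0L)
    stop("no intersection: no chains could be formed")
  npts <- vapply(chains, function(ch) nrow(ch$points), 1L)
  zext <- vapply(chains, function(ch) diff(range(ch$points[, 2])), 1)
  ok <- npts >= 3L
  if (!any(ok))
    stop("degenerate section: only chains with fewer than 3 points")
  best <- which(ok)[which.max(zext[ok])]
  ch <- chains[[best]]
  pts <- ch$points
  closed <- ch$closed
  if (closed) {
    pts <- open_loop(pts, buccal = buccal_side)
  }
  if (pts[1, 2] < pts[nrow(pts), 2]) pts <- pts[rev(seq_len(nrow(pts))), ]
  pts <- drop_duplicate_points(pts, 1e-9)
  if (nrow(pts) < 3L)
    stop("degenerate section: fewer than 3 distinct points after chaining")
  cross_section(pts,
                plane = list(origin = c(plane_x_offset, 0, 0),
                             normal = c(1, 0, 0)),
                site_id = site_id, closed = closed)
}

# Intersect every triangle with the plane x = off; return segment endpoints
# as a matrix with columns y1, z1, y2, z2.
plane_triangle_segments <- function(mesh, off, tol) {
  v <- mesh$vertices; f <- mesh$faces
  d <- v[, 1] - off
  # nudge vertices lying exactly on the plane so every crossing is a clean
  # edge crossing; displacement far below chaining tolerance
  d[abs(d) < 1e-12] <- 1e-12
  dm <- matrix(d[f], ncol = 3L)
  crosses <- !(rowSums(dm > 0) == 3L | rowSums(dm < 0) == 3L)
  if (!any(crosses)) return(NULL)
  fidx <- which(crosses)
  out <- matrix(NA_real_, nrow = length(fidx), ncol = 4L)
  for (k in seq_along(fidx)) {
    tri <- f[fidx[k], ]
    dd <- d[tri]
    pts <- matrix(NA_real_, 0L, 2L)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      da <- dd[e[1]]; db <- dd[e[2]]
      if ((da > 0) != (db > 0)) {
        t <- da / (da - db)
        p <- v[tri[e[1]], ] + t * (v[tri[e[2]], ] - v[tri[e[1]], ])
        pts <- rbind(pts, p[2:3])
      }
    }
    if (nrow(pts) == 2L) out[k, ] <- c(pts[1, ], pts[2, ])
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

# Chain unordered segments into polylines by endpoint coincidence.
chain_segments <- function(segs, tol) {
  ends <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  uid <- match(key, unique(key))
  n <- nrow(segs)
  a <- uid[seq_len(n)]; b <- uid[n + seq_len(n)]
  keep <- a != b                       # drop zero-length slivers
  a <- a[keep]; b <- b[keep]
  coords <- ends[match(seq_len(max(uid)), uid), , drop = FALSE]
  deg <- tabulate(c(a, b), nbins = max(uid))
  used <- rep(FALSE, length(a))
  chains <- list()
  walk <- function(start) {
    path <- start
    cur <- start
    prev <- -1L
    repeat {
      nxt <- NA_integer_
      for (j in which(a == cur | b == cur)) {
        if (used[j]) next
        cand <- if (a[j] == cur) b[j] else a[j]
        used[j] <<- TRUE
        nxt <- cand
        break
      }
      if (is.na(nxt)) break
      path <- c(path, nxt)
      prev <- cur
      cur <- nxt
      if (cur == start) break
    }
    path
  }
  # open chains first (start at degree-1 nodes), then leftover loops
  for (s in which(deg == 1L)) {
    if (all(used[a == s | b == s])) next
    path <- walk(s)
    chains[[length(chains) + 1L]] <-
      list(points = coords[path, , drop = FALSE], closed = FALSE)
  }
  repeat {
    j <- which(!used)[1]
    if (is.na(j)) break
    path <- walk(a[j])
    closed <- length(path) > 2L && path[1] == path[length(path)]
    pts <- coords[path, , drop = FALSE]
    if (closed) pts <- pts[-nrow(pts), , drop = FALSE]
    chains[[length(chains) + 1L]] <- list(points = pts, closed = closed)
  }
  chains
}

# Cut a closed loop at its extreme-z points; keep the buccal (larger mean y)
# sub-chain, or open at the coronal extreme when buccal = FALSE.
open_loop <- function(pts, buccal = TRUE) {
  n <- nrow(pts)
  i_top <- which.max(pts[, 2])
  i_bot <- which.min(pts[, 2])
  if (!buccal) {
    return(pts[c(i_top:n, seq_len(i_top - 1L)), , drop = FALSE])
  }
  idx <- seq_len(n)
  if (i_top == i_bot) return(pts)
  path1 <- if (i_top <= i_bot) i_top:i_bot else c(i_top:n, 1L:i_bot)
  path2 <- if (i_bot <= i_top) i_bot:i_top else c(i_bot:n, 1L:i_top)
  m1 <- mean(pts[path1, 1]); m2 <- mean(pts[path2, 1])
  pts[if (m1 >= m2) path1 else path2, , drop = FALSE]
}

drop_duplicate_points <- function(pts, tol) {
  if (nrow(pts) < 2L) return(pts)
  gaps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  pts[c(TRUE, gaps > tol), , drop = FALSE]
}

#' Write a cross-section polyline to CSV
#'
#' Columns: `s_index`, `y_mm`, `z_mm`. Values are written at full precision;
#' rounding to 0.01 mm happens only in display contexts.
#'
#' @param section a [cross_section()].
#' @param path output CSV path.
#' @export
write_polyline <- function(section, path) {
  df <- data.frame(s_index = seq_len(nrow(section$points)) - 1L,
                   y_mm = section$points[, 1],
                   z_mm = section$points[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cross-section polyline from CSV
#'
#' Accepts the [write_polyline()] dialect (`s_index,y_mm,z_mm`) or plain
#' 2-column whitespace text (y z per line).
#'
#' @param path input path.
#' @param site_id label for the resulting section.
#' @return a [cross_section()].
#' @export
read_polyline <- function(path, site_id = basename(path)) {
  first <- readLines(path, n = 1L)
  if (grepl("y_mm", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    pts <- cbind(df$y_mm, df$z_mm)
  } else {
    df <- utils::read.table(path)
    pts <- as.matrix(df[, 1:2])
  }
  cross_section(pts, site_id = site_id)
}
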