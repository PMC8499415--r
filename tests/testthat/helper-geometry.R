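# Shared fixtures, built in code.

# unit cube as 12 triangles
cube_mesh <- function() {
  v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  dental_mesh(v, f)
}

# UV-sphere of radius r centred at the origin
sphere_mesh <- function(r = 5, n_lat = 24, n_lon = 48) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  v <- matrix(NA_real_, (n_lat + 1L) * n_lon, 3L)
  for (i in seq_len(n_lat + 1L))
    for (j in seq_len(n_lon))
      v[idx(i, j), ] <- r * c(cos(lat[i]) * cos(lon[j]),
                              cos(lat[i]) * sin(lon[j]), sin(lat[i]))
  f <- list()
  for (i in seq_len(n_lat))
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      f[[length(f) + 1L]] <- c(a, b, c2)
      f[[length(f) + 1L]] <- c(b, d, c2)
    }
  m <- merge_verts(v, do.call(rbind, f))
  dental_mesh(m$vertices, m$faces)
}

# local duplicate-merge (poles/seams), independent of package internals
merge_verts <- function(v, f, tol = 1e-9) {
  key <- apply(round(v / tol), 1L, paste, collapse = ",")
  map <- match(key, key[!duplicated(key)])
  keep <- !duplicated(key)
  f2 <- matrix(map[f], ncol = 3L)
  ok <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  list(vertices = v[keep, , drop = FALSE], faces = f2[ok, , drop = FALSE])
}

# Independent constant-curvature turtle: emits points of an arc chain under
# the package sign convention (positive kappa = convex, heading' = -kappa).
# Closed-form per segment; no package code involved.
arc_chain_points <- function(kappas, spans, theta0 = -pi / 2, step = 0.01,
                             p0 = c(0, 0)) {
  pts <- matrix(p0, 1L, 2L)
  th <- theta0
  for (seg in seq_along(kappas)) {
    k <- kappas[seg]; L <- spans[seg]
    ss <- seq(step, L, by = step)
    w <- -k
    if (abs(w) < 1e-14) {
      new <- cbind(pts[nrow(pts), 1] + ss * cos(th),
                   pts[nrow(pts), 2] + ss * sin(th))
    } else {
      new <- cbind(pts[nrow(pts), 1] + (sin(th + w * ss) - sin(th)) / w,
                   pts[nrow(pts), 2] - (cos(th + w * ss) - cos(th)) / w)
    }
    pts <- rbind(pts, new)
    th <- th + w * L
  }
  pts
}

# segment boundaries (arc lengths) of an arc chain built as above
arc_chain_breaks <- function(spans) cumsum(spans)

# forge a minimal curvature_profile for detection unit tests
fake_profile <- function(kappa, h = 0.01, boundary_n = 5L) {
  n <- length(kappa)
  s <- (seq_len(n) - 1L) * h
  # points: z strictly decreasing so orientation checks behave
  pts <- cbind(rep(0, n), -s)
  boundary <- rep(FALSE, n)
  boundary[c(seq_len(boundary_n), n + 1L - seq_len(boundary_n))] <- TRUE
  structure(list(curve = structure(list(s = s, points = pts, h = h),
                                   class = "sampled_curve"),
                 kappa = kappa, boundary = boundary),
            class = "curvature_profile")
}

# full pipeline: section/points -> curvature profile
run_pipeline <- function(section, smoothing = 0, h = 0.01) {
  signed_curvature(resample_curve(fit_spline(section, smoothing), h))
}

max_edge_len <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  max(sqrt(pmax(rowSums((v[f[, 1], ] - v[f[, 2], ])^2),
                rowSums((v[f[, 2], ] - v[f[, 3], ])^2),
                rowSums((v[f[, 3], ] - v[f[, 1], ])^2))))
}
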