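#' Fit a parametric cubic spline to a cross-section polyline
#'
#' The two coordinates are fitted as cubic splines of the cumulative
#' chord-length parameter. `smoothing` is the maximal allowed distance (mm)
#' between an input point and the fitted curve: 0 interpolates exactly; a
#' positive value fits a penalised smoothing spline whose penalty is chosen
#' (by bisection on the log penalty) as large as possible while every input
#' point stays within `smoothing` of its fitted position. The default 0.005 mm
#' is half the downstream 0.01 mm resampling step.
#'
#' @param polyline a [cross_section()] (or 2-column matrix) with >= 4 distinct
#'   points.
#' @param smoothing maximal point-to-curve deviation bound in mm; 0 =
#'   interpolation.
#' @return object of class `tooth_spline`: evaluators `ev_y(t, deriv)`,
#'   `ev_z(t, deriv)` for deriv 0..2, and the parameter range.
#' @export
fit_spline <- function(polyline, smoothing = 0.005) {
  pts <- if (inherits(polyline, "cross_section")) polyline$points
         else as.matrix(polyline)
  pts <- drop_duplicate_points(pts, 1e-9)
  if (nrow(pts) < 4L)
    stop("degenerate input: spline fit needs at least 4 distinct points")
  if (!is.numeric(smoothing) || smoothing < 0)
    stop("smoothing must be a non-negative deviation bound in mm")
  chord <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
  t <- c(0, cumsum(chord))
  if (smoothing == 0) {
    fy <- stats::splinefun(t, pts[, 1], method = "fmm")
    fz <- stats::splinefun(t, pts[, 2], method = "fmm")
    ev_y <- function(x, deriv = 0L) fy(x, deriv = deriv)
    ev_z <- function(x, deriv = 0L) fz(x, deriv = deriv)
  } else {
    fit_pair <- function(lambda) {
      sy <- stats::smooth.spline(t, pts[, 1], lambda = lambda,
                                 all.knots = TRUE, keep.data = FALSE)
      sz <- stats::smooth.spline(t, pts[, 2], lambda = lambda,
                                 all.knots = TRUE, keep.data = FALSE)
      dev <- sqrt((stats::predict(sy, t)$y - pts[, 1])^2 +
                    (stats::predict(sz, t)$y - pts[, 2])^2)
      list(sy = sy, sz = sz, max_dev = max(dev))
    }
    # largest log-penalty whose max deviation respects the bound
    lo <- -20; hi <- 2
    best <- fit_pair(10^lo)
    if (best$max_dev > smoothing)
      stop("cannot satisfy smoothing bound even at near-zero penalty")
    for (iter in seq_len(16L)) {
      mid <- (lo + hi) / 2
      f <- fit_pair(10^mid)
      if (f$max_dev <= smoothing) {
        lo <- mid; best <- f
      } else hi <- mid
    }
    sy <- best$sy; sz <- best$sz
    ev_y <- function(x, deriv = 0L) stats::predict(sy, x, deriv = deriv)$y
    ev_z <- function(x, deriv = 0L) stats::predict(sz, x, deriv = deriv)$y
  }
  structure(list(ev_y = ev_y, ev_z = ev_z, t_min = 0, t_max = t[length(t)],
                 knots = t, smoothing = smoothing),
            class = "tooth_spline")
}

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

.gl16 <- gauss_legendre(16L)

spline_speed <- function(handle, t) {
  sqrt(handle$ev_y(t, 1L)^2 + handle$ev_z(t, 1L)^2)
}

# integral of speed over [t0, t1] by 16-point Gauss-Legendre
arc_panel <- function(handle, t0, t1) {
  half <- (t1 - t0) / 2
  mid <- (t1 + t0) / 2
  sum(.gl16$w * spline_speed(handle, mid + half * .gl16$x)) * half
}

#' Resample a fitted curve at uniform arc length
#'
#' Samples the spline at arc lengths 0, h, 2h, ... up to the total length.
#' Arc length is computed by composite Gauss-Legendre quadrature of the
#' parametric speed and inverted per sample by safeguarded Newton iteration
#' to 1e-9 mm.
#'
#' @param handle a `tooth_spline` from [fit_spline()].
#' @param h arc-length step in mm (default 0.01, the working resolution).
#' @return object of class `sampled_curve`: `s` (arc length), `points`
#'   (y, z), `t` (parameter values), `h`, and the spline handle.
#' @export
resample_curve <- function(handle, h = 0.01) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a positive step in mm")
  K <- max(64L, 4L * length(handle$knots))
  tg <- seq(handle$t_min, handle$t_max, length.out = K + 1L)
  panel <- vapply(seq_len(K),
                  function(i) arc_panel(handle, tg[i], tg[i + 1L]), 1)
  S <- c(0, cumsum(panel))
  L <- S[K + 1L]
  targets <- seq(0, by = h, length.out = floor(L / h + 1e-9) + 1L)
  tt <- numeric(length(targets))
  for (i in seq_along(targets)) {
    s0 <- targets[i]
    k <- findInterval(s0, S, rightmost.closed = TRUE)
    k <- min(max(k, 1L), K)
    lo <- tg[k]; hi <- tg[k + 1L]
    t_cur <- lo + (hi - lo) *
      if (panel[k] > 0) (s0 - S[k]) / panel[k] else 0.5
    for (it in seq_len(50L)) {
      err <- S[k] + arc_panel(handle, tg[k], t_cur) - s0
      if (abs(err) < 1e-9) break
      sp <- spline_speed(handle, t_cur)
      t_new <- t_cur - err / max(sp, 1e-12)
      if (t_new <= lo || t_new >= hi) t_new <- (lo + hi) / 2
      if (err > 0) hi <- t_cur else lo <- t_cur
      t_cur <- t_new
    }
    tt[i] <- t_cur
  }
  pts <- cbind(handle$ev_y(tt), handle$ev_z(tt))
  structure(list(s = targets, points = pts, t = tt, h = h,
                 length = L, handle = handle),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %d samples, h = %g mm, length %.3f mm\n",
              length(x$s), x$h, x$length))
  invisible(x)
}

#' Signed curvature along a resampled cross-section
#'
#' Curvature is evaluated from the analytic first and second spline
#' derivatives at each sample (never from finite differences of the resampled
#' points). Sign convention: with the chain ordered coronal to apical and the
#' tooth/gingiva tissue on its right, positive curvature marks a locally
#' convex surface and negative a concave one, so anatomical landmark
#' concavities carry negative curvature. The first and last `boundary_n`
#' samples are flagged as boundary, where spline end conditions distort
#' curvature, and are excluded from landmark search.
#'
#' @param curve a `sampled_curve` from [resample_curve()].
#' @param boundary_n number of samples flagged at each end (default 5).
#' @return object of class `curvature_profile`: the curve, `kappa` (1/mm),
#'   and a logical `boundary` flag per sample.
#' @export
signed_curvature <- function(curve, boundary_n = 5L) {
  if (!inherits(curve, "sampled_curve")) stop("curve must be a sampled_curve")
  n <- length(curve$s)
  if (n < 5L) stop("degenerate input: need at least 5 samples")
  h <- curve$handle
  tt <- curve$t
  d1y <- h$ev_y(tt, 1L); d1z <- h$ev_z(tt, 1L)
  d2y <- h$ev_y(tt, 2L); d2z <- h$ev_z(tt, 2L)
  speed <- sqrt(d1y^2 + d1z^2)
  # negated standard formula: under the coronal->apical, tissue-right
  # orientation this makes convex surfaces positive (comb convention)
  kappa <- -(d1y * d2z - d1z * d2y) / pmax(speed, 1e-300)^3
  boundary <- rep(FALSE, n)
  bn <- min(boundary_n, floor((n - 1) / 2))
  if (bn > 0) boundary[c(seq_len(bn), n + 1L - seq_len(bn))] <- TRUE
  structure(list(curve = curve, kappa = kappa, boundary = boundary),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  k <- x$kappa[!x$boundary]
  cat(sprintf(
    "<curvature_profile> %d samples, kappa in [%.3f, %.3f] 1/mm\n",
    length(x$kappa), min(k), max(k)))
  invisible(x)
}

#' Curvature comb geometry
#'
#' For each sample a segment normal to the curve with length
#' `scale * |kappa|`, tagged convex (positive kappa) or concave (negative),
#' reproducing the colour-coded comb plots used to visualise curvature on a
#' cross-section. Teeth point along `kappa * n_left`, i.e. outward on convex
#' stretches and toward the tissue on concave ones.
#'
#' @param profile a `curvature_profile`.
#' @param scale comb scale in mm per (1/mm) of curvature.
#' @return data.frame with the sample point, tip point, kappa and side tag.
#' @export
curvature_comb <- function(profile, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be positive")
  cv <- profile$curve
  h <- cv$handle
  d1y <- h$ev_y(cv$t, 1L); d1z <- h$ev_z(cv$t, 1L)
  speed <- pmax(sqrt(d1y^2 + d1z^2), 1e-300)
  nL <- cbind(-d1z, d1y) / speed
  tip <- cv$points + scale * profile$kappa * nL
  data.frame(s_mm = cv$s,
             y_mm = cv$points[, 1], z_mm = cv$points[, 2],
             y_tip_mm = tip[, 1], z_tip_mm = tip[, 2],
             kappa_per_mm = profile$kappa,
             side = ifelse(profile$kappa > 0, "convex",
                           ifelse(profile$kappa < 0, "concave", "flat")),
             boundary = profile$boundary)
}

#' Export a curvature profile as CSV
#'
#' Columns: `s_mm`, `y_mm`, `z_mm`, `kappa_per_mm`, `boundary_flag`.
#'
#' @param profile a `curvature_profile`.
#' @param path output CSV path.
#' @export
write_curvature_profile <- function(profile, path) {
  cv <- profile$curve
  utils::write.csv(data.frame(
    s_mm = cv$s, y_mm = cv$points[, 1], z_mm = cv$points[, 2],
    kappa_per_mm = profile$kappa,
    boundary_flag = as.integer(profile$boundary)),
    path, row.names = FALSE)
  invisible(path)
}
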