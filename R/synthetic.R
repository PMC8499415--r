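#' Parametric specification of a synthetic cross-section profile
#'
#' Describes a bucco-oral cross-section as a chain of constant-curvature
#' arcs (convex crown, near-straight root, convex gingiva) joined through
#' the two landmark concavities, each built from two linear-curvature ramps
#' meeting at the curvature peak. The peak of the CEJ concavity carries
#' exactly `-|cej_kappa|` and the peak of the GM concavity `-|gm_kappa|`;
#' those peaks are the ground-truth landmarks, and the root segment length
#' is solved so their Euclidean distance equals `recession_depth` to 1e-6 mm.
#' Tangent (G1) continuity holds everywhere (the ramps are even G2 at their
#' outer junctions in curvature value).
#'
#' Default curvature magnitudes sit at the clinically observed medians
#' (CEJ ~ 1, GM ~ 4.4 1/mm) and the default depth at the observed median
#' 1.9 mm. Feature spans default to fixed turn angles scaled by 1/kappa,
#' capped by the recession depth so the geometry stays feasible.
#'
#' @param crown_kappa convex crown curvature (1/mm), > 0.
#' @param cej_kappa CEJ peak curvature magnitude (1/mm); stored negative.
#' @param cej_arc_span total span (mm) of the CEJ concavity feature;
#'   NULL = automatic.
#' @param root_kappa root surface curvature (1/mm), near 0.
#' @param recession_depth ground-truth CEJ-GM distance (mm).
#' @param gm_kappa GM peak curvature magnitude (1/mm); stored negative.
#' @param gm_arc_span total span (mm) of the GM concavity; NULL = automatic.
#' @param gingiva_kappa convex gingival surface curvature (1/mm), > 0.
#' @param crown_span,gingiva_span spans (mm) of the outer arcs.
#' @param root_tilt heading of the root relative to straight down (rad).
#' @param noise_sigma Gaussian point noise sd (mm) added to sampled points.
#' @param seed integer seed used when noise is drawn.
#' @return object of class `profile_spec`.
#' @export
profile_spec <- function(crown_kappa = 0.3,
                         cej_kappa = 0.99,
                         cej_arc_span = NULL,
                         root_kappa = 0.02,
                         recession_depth = 1.90,
                         gm_kappa = 4.39,
                         gm_arc_span = NULL,
                         gingiva_kappa = 0.5,
                         crown_span = 3,
                         gingiva_span = 2,
                         root_tilt = 0.05,
                         noise_sigma = 0,
                         seed = NULL) {
  kc <- abs(cej_kappa); kg <- abs(gm_kappa)
  if (crown_kappa <= 0 || gingiva_kappa <= 0)
    stop("incompatible spec: crown_kappa and gingiva_kappa must be convex (> 0)")
  if (kc <= 0 || kg <= 0)
    stop("incompatible spec: landmark curvature magnitudes must be positive")
  if (recession_depth <= 0)
    stop("incompatible spec: recession_depth must be positive")
  if (noise_sigma < 0) stop("incompatible spec: noise_sigma must be >= 0")
  if (is.null(cej_arc_span))
    cej_arc_span <- 2 * min(0.3 / kc, recession_depth / 4)
  if (is.null(gm_arc_span))
    gm_arc_span <- 2 * min(0.7 / kg, recession_depth / 6)
  if (cej_arc_span <= 0 || gm_arc_span <= 0 ||
        crown_span <= 0 || gingiva_span <= 0)
    stop("incompatible spec: all spans must be positive")
  structure(list(crown_kappa = crown_kappa, cej_kappa = -kc,
                 cej_arc_span = cej_arc_span, root_kappa = root_kappa,
                 recession_depth = recession_depth, gm_kappa = -kg,
                 gm_arc_span = gm_arc_span, gingiva_kappa = gingiva_kappa,
                 crown_span = crown_span, gingiva_span = gingiva_span,
                 root_tilt = root_tilt, noise_sigma = noise_sigma,
                 seed = seed),
            class = "profile_spec")
}

# Segment table: columns s0, s1, k0, k1 — signed curvature linear in s.
build_segments <- function(spec, root_len) {
  fc <- spec$cej_arc_span / 2
  fg <- spec$gm_arc_span / 2
  spans <- c(spec$crown_span, fc, fc, root_len, fg, fg, spec$gingiva_span)
  k0 <- c(spec$crown_kappa, spec$crown_kappa, spec$cej_kappa,
          spec$root_kappa, spec$root_kappa, spec$gm_kappa,
          spec$gingiva_kappa)
  k1 <- c(spec$crown_kappa, spec$cej_kappa, spec$root_kappa,
          spec$root_kappa, spec$gm_kappa, spec$gingiva_kappa,
          spec$gingiva_kappa)
  s1 <- cumsum(spans)
  data.frame(name = c("crown", "cej_in", "cej_out", "root",
                      "gm_in", "gm_out", "gingiva"),
             s0 = c(0, utils::head(s1, -1L)), s1 = s1, k0 = k0, k1 = k1)
}

# analytic signed curvature of the chain at arc length s (vectorised)
segments_kappa <- function(seg, s) {
  out <- numeric(length(s))
  for (i in seq_len(nrow(seg))) {
    inb <- s >= seg$s0[i] & (s <= seg$s1[i] + 1e-12)
    if (i < nrow(seg)) inb <- inb & s < seg$s1[i]
    u <- (s[inb] - seg$s0[i]) / (seg$s1[i] - seg$s0[i])
    out[inb] <- seg$k0[i] + u * (seg$k1[i] - seg$k0[i])
  }
  out
}

# tangent angle theta(s): theta' = -kappa, piecewise quadratic, analytic
segments_theta <- function(seg, theta0, s) {
  L <- seg$s1 - seg$s0
  turn <- -(seg$k0 + seg$k1) / 2 * L       # theta change over each segment
  th_start <- theta0 + c(0, cumsum(utils::head(turn, -1L)))
  out <- numeric(length(s))
  for (i in seq_len(nrow(seg))) {
    inb <- s >= seg$s0[i] - 1e-12 & s <= seg$s1[i] + 1e-12
    if (i < nrow(seg)) inb <- inb & s < seg$s1[i]
    u <- s[inb] - seg$s0[i]
    out[inb] <- th_start[i] -
      (seg$k0[i] * u + (seg$k1[i] - seg$k0[i]) * u^2 / (2 * L[i]))
  }
  out
}

.gl20 <- gauss_legendre(20L)

# positions of the chain at arc lengths s (sorted not required)
segments_position <- function(seg, theta0, s) {
  L <- seg$s1 - seg$s0
  th <- function(x) segments_theta(seg, theta0, x)
  quad <- function(a, b) {
    half <- (b - a) / 2; mid <- (a + b) / 2
    ang <- th(mid + half * .gl20$x)
    c(sum(.gl20$w * cos(ang)), sum(.gl20$w * sin(ang))) * half
  }
  # segment start positions, splitting long segments for quadrature accuracy
  seg_pos <- matrix(0, nrow(seg) + 1L, 2L)
  for (i in seq_len(nrow(seg))) {
    nsub <- max(1L, ceiling(L[i] / 0.5))
    bp <- seq(seg$s0[i], seg$s1[i], length.out = nsub + 1L)
    acc <- seg_pos[i, ]
    for (j in seq_len(nsub)) acc <- acc + quad(bp[j], bp[j + 1L])
    seg_pos[i + 1L, ] <- acc
  }
  out <- matrix(NA_real_, length(s), 2L)
  for (k in seq_along(s)) {
    i <- findInterval(s[k], c(seg$s0, seg$s1[nrow(seg)]),
                      rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    base <- seg_pos[i, ]
    a <- seg$s0[i]; b <- s[k]
    nsub <- max(1L, ceiling((b - a) / 0.5))
    bp <- seq(a, b, length.out = nsub + 1L)
    acc <- base
    if (b > a) for (j in seq_len(nsub)) acc <- acc + quad(bp[j], bp[j + 1L])
    out[k, ] <- acc
  }
  out
}

chain_theta0 <- function(spec, root_len) {
  # choose the start heading so the root begins at -pi/2 + root_tilt
  seg <- build_segments(spec, root_len)
  pre <- seg[seg$name %in% c("crown", "cej_in", "cej_out"), ]
  turn_pre <- sum(-(pre$k0 + pre$k1) / 2 * (pre$s1 - pre$s0))
  (-pi / 2 + spec$root_tilt) - turn_pre
}

landmark_s <- function(spec, root_len) {
  c(cej = spec$crown_span + spec$cej_arc_span / 2,
    gm = spec$crown_span + spec$cej_arc_span + root_len +
      spec$gm_arc_span / 2)
}

landmark_distance <- function(spec, root_len) {
  th0 <- chain_theta0(spec, root_len)
  seg <- build_segments(spec, root_len)
  p <- segments_position(seg, th0, landmark_s(spec, root_len))
  sqrt(sum((p[1, ] - p[2, ])^2))
}

# root segment length such that the CEJ-GM distance equals recession_depth.
# Only the constant-curvature root segment depends on the unknown length:
# the CEJ-side piece is fixed and the GM-side piece is a fixed local vector
# rotated by the root's heading change, so each distance evaluation is
# closed-form (verified against landmark_distance in the tests).
landmark_distance_fun <- function(spec) {
  ref <- 1
  seg1 <- build_segments(spec, ref)
  th0 <- chain_theta0(spec, ref)
  s_cejmid <- spec$crown_span + spec$cej_arc_span / 2
  s_rs <- spec$crown_span + spec$cej_arc_span        # root start
  s_re <- s_rs + ref                                 # root end (reference)
  s_gmmid <- s_re + spec$gm_arc_span / 2
  pos <- segments_position(seg1, th0, c(s_cejmid, s_rs, s_re, s_gmmid))
  A <- pos[2, ] - pos[1, ]
  B_ref <- pos[4, ] - pos[3, ]
  th_rs <- -pi / 2 + spec$root_tilt
  krt <- spec$root_kappa
  function(lr) {
    w <- -krt
    D <- if (abs(w) < 1e-12) lr * c(cos(th_rs), sin(th_rs)) else
      c((sin(th_rs + w * lr) - sin(th_rs)) / w,
        -(cos(th_rs + w * lr) - cos(th_rs)) / w)
    dth <- -krt * (lr - ref)       # rotation of the GM-side piece
    B <- c(cos(dth) * B_ref[1] - sin(dth) * B_ref[2],
           sin(dth) * B_ref[1] + cos(dth) * B_ref[2])
    sqrt(sum((A + D + B)^2))
  }
}

solve_root_length <- function(spec, dist_of = landmark_distance_fun(spec)) {
  f <- function(lr) dist_of(lr) - spec$recession_depth
  lo <- 0.02
  if (f(lo) > 0)
    stop(sprintf(paste0(
      "incompatible spec: recession_depth %.3f mm is below the minimal ",
      "CEJ-GM separation %.3f mm imposed by the arc spans"),
      spec$recession_depth, landmark_distance(spec, lo)))
  hi <- max(4 * spec$recession_depth, 2)
  while (f(hi) < 0 && hi < 200) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic cross-section profile with ground truth
#'
#' Builds the arc/ramp chain of [profile_spec()], solves the root length so
#' the ground-truth CEJ-GM distance equals `recession_depth`, samples the
#' chain exactly at uniform arc length, optionally adds Gaussian point noise
#' (measurement noise, applied after exact sampling), and returns the
#' polyline together with the exact landmark ground truth and the analytic
#' curvature field. Deterministic for a fixed seed.
#'
#' @param spec a [profile_spec()].
#' @param step arc-length sampling step of the emitted polyline (mm).
#' @return object of class `synthetic_profile`: `section` (a
#'   [cross_section()]), `s` sample positions, `segments` table, `truth`
#'   (cej/gm s, point, kappa; depth), `root_len`, and the spec.
#' @export
generate_profile <- function(spec, step = 0.01) {
  stopifnot(inherits(spec, "profile_spec"))
  if (step <= 0) stop("step must be positive")
  root_len <- solve_root_length(spec)
  seg <- build_segments(spec, root_len)
  th0 <- chain_theta0(spec, root_len)
  total <- seg$s1[nrow(seg)]
  s <- seq(0, by = step, length.out = floor(total / step + 1e-9) + 1L)
  pts <- segments_position(seg, th0, s)
  ls <- landmark_s(spec, root_len)
  lp <- segments_position(seg, th0, ls)
  truth <- list(
    cej = list(s = unname(ls["cej"]), point = lp[1, ],
               kappa = spec$cej_kappa),
    gm = list(s = unname(ls["gm"]), point = lp[2, ],
              kappa = spec$gm_kappa),
    depth = sqrt(sum((lp[1, ] - lp[2, ])^2)))
  if (spec$noise_sigma > 0) {
    pts <- pts + with_seed(spec$seed, matrix(
      stats::rnorm(length(pts), 0, spec$noise_sigma), ncol = 2L))
  }
  section <- cross_section(pts, site_id = "synthetic")
  structure(list(section = section, s = s, segments = seg,
                 truth = truth, root_len = root_len, spec = spec,
                 theta0 = th0),
            class = "synthetic_profile")
}

#' Analytic curvature of a synthetic profile at given arc lengths
#'
#' @param profile a `synthetic_profile`.
#' @param s arc-length positions (mm).
#' @return signed curvature values (1/mm), exact by construction.
#' @export
synthetic_kappa <- function(profile, s) {
  segments_kappa(profile$segments, s)
}

#' @export
print.synthetic_profile <- function(x, ...) {
  cat(sprintf(
    "<synthetic_profile> length %.2f mm, depth %.3f mm, kappa CEJ %.2f / GM %.2f 1/mm\n",
    max(x$s), x$truth$depth, x$truth$cej$kappa, x$truth$gm$kappa))
  invisible(x)
}

# run code with a temporary RNG state seeded by `seed` (NULL = current RNG)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

lognormal_from_quantiles <- function(med, q, p) {
  sdlog <- (log(q[2]) - log(q[1])) / (stats::qnorm(p[2]) - stats::qnorm(p[1]))
  c(meanlog = log(med), sdlog = sdlog)
}

#' Generate a cohort of synthetic recession sites
#'
#' Per-site parameters are drawn from log-normal distributions
#' moment-matched to the clinically reported summaries: CEJ curvature
#' magnitude median 0.99 1/mm (5th-95th percentile 0.32-2.30), GM magnitude
#' median 4.39 (1.98-9.14), recession depth median 1.90 mm (IQR 1.25-2.62).
#' Depth draws are floored at the minimal geometrically feasible separation
#' of the drawn arc spans (rarely active; recorded per site). Reproducible
#' by seed.
#'
#' @param n number of sites (the reference sample has 60).
#' @param seed integer seed.
#' @param cej_kappa_median,cej_kappa_q90 CEJ magnitude median and 5th/95th
#'   percentiles.
#' @param gm_kappa_median,gm_kappa_q90 GM magnitude median and 5th/95th
#'   percentiles.
#' @param depth_median,depth_iqr depth median and 25th/75th percentiles.
#' @param noise_sigma per-site point noise sd (mm).
#' @param step sampling step (mm).
#' @param profiles generate the sampled polylines (default); FALSE computes
#'   only the ground-truth table, much faster for examiner-model
#'   simulations that never touch the sampled points.
#' @return object of class `synthetic_cohort`: `profiles` (named list,
#'   empty when `profiles = FALSE`), `truth` data.frame (site_id, kappa_cej,
#'   kappa_gm, depth, s_cej, s_gm, total_s), and the distribution parameters
#'   used.
#' @export
generate_cohort <- function(n = 60, seed = 1,
                            cej_kappa_median = 0.99,
                            cej_kappa_q90 = c(0.32, 2.30),
                            gm_kappa_median = 4.39,
                            gm_kappa_q90 = c(1.98, 9.14),
                            depth_median = 1.90,
                            depth_iqr = c(1.25, 2.62),
                            noise_sigma = 0, step = 0.01,
                            profiles = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (any(c(cej_kappa_median, gm_kappa_median, depth_median) <= 0) ||
        any(c(cej_kappa_q90, gm_kappa_q90, depth_iqr) <= 0))
    stop("distribution parameters must be positive")
  if (cej_kappa_q90[1] >= cej_kappa_q90[2] ||
        gm_kappa_q90[1] >= gm_kappa_q90[2] || depth_iqr[1] >= depth_iqr[2])
    stop("quantile pairs must be increasing")
  par_cej <- lognormal_from_quantiles(cej_kappa_median, cej_kappa_q90,
                                      c(0.05, 0.95))
  par_gm <- lognormal_from_quantiles(gm_kappa_median, gm_kappa_q90,
                                     c(0.05, 0.95))
  par_d <- lognormal_from_quantiles(depth_median, depth_iqr, c(0.25, 0.75))
  draws <- with_seed(seed, list(
    kc = stats::rlnorm(n, par_cej["meanlog"], par_cej["sdlog"]),
    kg = stats::rlnorm(n, par_gm["meanlog"], par_gm["sdlog"]),
    d = stats::rlnorm(n, par_d["meanlog"], par_d["sdlog"]),
    noise_seeds = sample.int(.Machine$integer.max, n)))
  prof_list <- list(); rows <- list()
  for (i in seq_len(n)) {
    sp <- profile_spec(cej_kappa = draws$kc[i], gm_kappa = draws$kg[i],
                       recession_depth = draws$d[i],
                       noise_sigma = noise_sigma,
                       seed = draws$noise_seeds[i])
    # feasibility floor on depth, given the drawn spans
    dist_fun <- landmark_distance_fun(sp)
    min_sep <- dist_fun(0.02)
    floored <- FALSE
    if (sp$recession_depth <= min_sep + 0.01) {
      sp$recession_depth <- min_sep + 0.01
      floored <- TRUE
    }
    id <- sprintf("site%03d", i)
    if (profiles) {
      pr <- generate_profile(sp, step = step)
      pr$section$site_id <- id
      prof_list[[id]] <- pr
      depth_i <- pr$truth$depth
      ls <- landmark_s(sp, pr$root_len)
      total_i <- pr$segments$s1[nrow(pr$segments)]
    } else {
      rl <- solve_root_length(sp, dist_fun)
      depth_i <- dist_fun(rl)
      ls <- landmark_s(sp, rl)
      total_i <- build_segments(sp, rl)$s1[7L]
    }
    rows[[i]] <- data.frame(
      site_id = id, kappa_cej = -abs(draws$kc[i]),
      kappa_gm = -abs(draws$kg[i]), depth = depth_i,
      s_cej = unname(ls["cej"]), s_gm = unname(ls["gm"]),
      total_s = total_i, depth_floored = floored)
  }
  structure(list(profiles = prof_list, truth = do.call(rbind, rows),
                 params = list(cej = par_cej, gm = par_gm, depth = par_d,
                               n = n, seed = seed,
                               noise_sigma = noise_sigma)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d sites; median |kappa| CEJ %.2f, GM %.2f; median depth %.2f mm\n",
    nrow(x$truth), stats::median(abs(x$truth$kappa_cej)),
    stats::median(abs(x$truth$kappa_gm)), stats::median(x$truth$depth)))
  invisible(x)
}

#' Curvature-dependent examiner model
#'
#' A manual pick deviates from the true landmark along the curve by a draw
#' from Normal(0, sigma0 / max(|kappa|, kappa_floor)): the straighter the
#' local profile, the larger the pick scatter — the mechanism that makes CEJ
#' picks (low curvature) noisier than GM picks (high curvature). A zero
#' `sigma0` reproduces ground truth exactly.
#'
#' @param sigma0 scatter scale, mm * (1/mm) = dimensionless slope; at
#'   |kappa| = 1 1/mm the pick sd is `sigma0` mm.
#' @param kappa_floor lower bound on |kappa| in the scatter rule (1/mm).
#' @return object of class `examiner_model`.
#' @export
examiner_model <- function(sigma0 = 0.2, kappa_floor = 0.1) {
  if (sigma0 < 0 || kappa_floor <= 0)
    stop("sigma0 must be >= 0 and kappa_floor > 0")
  structure(list(sigma0 = sigma0, kappa_floor = kappa_floor),
            class = "examiner_model")
}

#' Simulate manual landmark picks for a cohort
#'
#' One pick per (site, landmark, examiner, round): the ground-truth arc
#' length plus a draw from the [examiner_model()]. CEJ picks use the site's
#' CEJ curvature and GM picks the GM curvature, so GM deviations are
#' systematically smaller. Picks are clamped to the curve.
#'
#' @param cohort a `synthetic_cohort`.
#' @param model an [examiner_model()].
#' @param examiners number of examiners (default 3).
#' @param rounds number of rounds per examiner (default 2).
#' @param seed integer seed.
#' @return data.frame: site_id, examiner, round, landmark, s (picked arc
#'   length, mm), true_deviation (mm, + coronal).
#' @export
simulate_examiner <- function(cohort, model = examiner_model(),
                              examiners = 3, rounds = 2, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(model, "examiner_model"))
  tr <- cohort$truth
  grid <- expand.grid(site = seq_len(nrow(tr)),
                      examiner = seq_len(examiners),
                      round = seq_len(rounds),
                      landmark = c("CEJ", "GM"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  kappa <- ifelse(grid$landmark == "CEJ",
                  abs(tr$kappa_cej[grid$site]), abs(tr$kappa_gm[grid$site]))
  sdv <- model$sigma0 / pmax(kappa, model$kappa_floor)
  dev <- with_seed(seed, stats::rnorm(nrow(grid), 0, sdv))
  s_true <- ifelse(grid$landmark == "CEJ",
                   tr$s_cej[grid$site], tr$s_gm[grid$site])
  s_pick <- pmin(pmax(s_true - dev, 0), tr$total_s[grid$site])
  data.frame(site_id = tr$site_id[grid$site],
             examiner = grid$examiner, round = grid$round,
             landmark = grid$landmark, s = s_pick,
             true_deviation = s_true - s_pick)
}

#' Extrude a synthetic profile into a minimal STL ribbon mesh
#'
#' Sweeps the 2D polyline a small width along the mesio-distal x-axis so the
#' mesh-sectioning stage can be integration-tested end to end: slicing the
#' ribbon at x = 0 recovers the profile.
#'
#' @param profile a `synthetic_profile`.
#' @param width extrusion width (mm).
#' @return a [dental_mesh()].
#' @export
profile_to_mesh <- function(profile, width = 2) {
  pts <- profile$section$points
  n <- nrow(pts)
  v <- rbind(cbind(-width / 2, pts), cbind(width / 2, pts))
  f <- matrix(0L, 2L * (n - 1L), 3L)
  for (i in seq_len(n - 1L)) {
    a <- i; b <- i + 1L; a2 <- n + i; b2 <- n + i + 1L
    f[2L * i - 1L, ] <- c(a, b, a2)
    f[2L * i, ] <- c(b, b2, a2)
  }
  dental_mesh(v, f)
}

#' Write cohort ground truth as JSON
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output path.
#' @export
write_cohort_truth <- function(cohort, path) {
  jsonlite::write_json(list(truth = cohort$truth, params = cohort$params),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
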