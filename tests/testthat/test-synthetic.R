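test_that("ground-truth depth and curvature hold by construction", {
  sp <- profile_spec(recession_depth = 1.90)
  pr <- generate_profile(sp)
  expect_equal(pr$truth$depth, 1.90, tolerance = 1e-6)
  expect_equal(sqrt(sum((pr$truth$cej$point - pr$truth$gm$point)^2)),
               1.90, tolerance = 1e-6)
  # analytic field at the ground-truth samples equals the spec magnitudes
  expect_equal(synthetic_kappa(pr, pr$truth$cej$s), -0.99,
               tolerance = 1e-6)
  expect_equal(synthetic_kappa(pr, pr$truth$gm$s), -4.39, tolerance = 1e-6)
  # constant-curvature segments carry exactly +/- 1/r
  seg <- pr$segments
  mid <- (seg$s0 + seg$s1) / 2
  expect_equal(synthetic_kappa(pr, mid[seg$name == "crown"]), 0.3)
  expect_equal(synthetic_kappa(pr, mid[seg$name == "root"]), 0.02)
  expect_equal(synthetic_kappa(pr, mid[seg$name == "gingiva"]), 0.5)
})

test_that("infeasible specs fail with a named constraint", {
  expect_error(generate_profile(
    profile_spec(cej_arc_span = 2, gm_arc_span = 1.5,
                 recession_depth = 0.5)),
    "recession_depth")
  expect_error(profile_spec(recession_depth = -1), "incompatible spec")
  expect_error(profile_spec(crown_kappa = -0.3), "incompatible spec")
  expect_error(profile_spec(noise_sigma = -0.1), "incompatible spec")
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_profile(profile_spec(noise_sigma = 0.005, seed = 99))
  b <- generate_profile(profile_spec(noise_sigma = 0.005, seed = 99))
  expect_identical(a$section$points, b$section$points)
  c2 <- generate_profile(profile_spec(noise_sigma = 0.005, seed = 100))
  expect_false(identical(a$section$points, c2$section$points))
})

test_that("fitted curvature matches the analytic field along the chain", {
  pr <- generate_profile(profile_spec())
  pf <- run_pipeline(pr$section)
  s <- pf$curve$s
  ramps <- pr$segments[grepl("_in|_out", pr$segments$name), ]
  near_ramp <- vapply(s, function(x)
    any(x >= ramps$s0 - 0.05 & x <= ramps$s1 + 0.05), TRUE)
  keep <- !pf$boundary & !near_ramp & s <= max(pr$s)
  expect_lt(max(abs(pf$kappa[keep] - synthetic_kappa(pr, s[keep]))), 1e-2)
})

test_that("cohort draws match the stated distributions", {
  co <- generate_cohort(n = 60, seed = 42)
  expect_length(co$profiles, 60L)
  expect_equal(nrow(co$truth), 60L)
  # moment-matching parameters recorded in the output
  expect_equal(unname(co$params$cej["meanlog"]), log(0.99))
  expect_equal(unname(co$params$depth["meanlog"]), log(1.90))
  co1 <- generate_cohort(n = 1, seed = 1)
  expect_length(co1$profiles, 1L)
  expect_error(generate_cohort(n = 0), "n must be")

  # truth-only cohorts agree with full ones
  fast <- generate_cohort(n = 10, seed = 7, profiles = FALSE)
  full <- generate_cohort(n = 10, seed = 7)
  expect_equal(fast$truth$depth, full$truth$depth, tolerance = 1e-9)
  expect_equal(fast$truth$s_gm, full$truth$s_gm, tolerance = 1e-9)
})

test_that("noise-free pipeline recovers every landmark and depth", {
  co <- generate_cohort(n = 8, seed = 31)
  for (id in names(co$profiles)) {
    pr <- co$profiles[[id]]
    det <- detect_landmarks(run_pipeline(pr$section))
    expect_lt(abs(det$cej$s - pr$truth$cej$s), 0.02)
    expect_lt(abs(det$gm$s - pr$truth$gm$s), 0.02)
    expect_lt(abs(recession_depth(det$cej, det$gm) - pr$truth$depth), 0.02)
  }
})

test_that("examiner model scatter follows sigma0 / max(|kappa|, floor)", {
  tr <- data.frame(site_id = "s1", kappa_cej = -0.5, kappa_gm = -4,
                   depth = 2, s_cej = 3, s_gm = 5, total_s = 50,
                   depth_floored = FALSE)
  co <- structure(list(profiles = list(), truth = tr, params = list()),
                  class = "synthetic_cohort")
  picks <- simulate_examiner(co, examiner_model(sigma0 = 0.1,
                                                kappa_floor = 0.1),
                             examiners = 1000, rounds = 1, seed = 5)
  cejs <- picks$true_deviation[picks$landmark == "CEJ"]
  expect_equal(sd(cejs), 0.1 / 0.5, tolerance = 0.05)
  gms <- picks$true_deviation[picks$landmark == "GM"]
  expect_equal(sd(gms), 0.1 / 4, tolerance = 0.05 * 4)

  zero <- simulate_examiner(co, examiner_model(sigma0 = 0),
                            examiners = 3, rounds = 2, seed = 6)
  expect_true(all(zero$true_deviation == 0))
  expect_true(all(zero$s[zero$landmark == "CEJ"] == 3))
})

test_that("CEJ deviations dominate GM deviations under defaults", {
  wins <- vapply(1:20, function(s) {
    co <- generate_cohort(n = 20, seed = s, profiles = FALSE)
    picks <- simulate_examiner(co, seed = s + 500)
    median(abs(picks$true_deviation[picks$landmark == "CEJ"])) >
      median(abs(picks$true_deviation[picks$landmark == "GM"]))
  }, TRUE)
  expect_equal(sum(wins), 20L)
})

test_that("profile extrudes to a mesh whose section recovers the profile", {
  pr <- generate_profile(profile_spec(crown_span = 1.5, gingiva_span = 0.5))
  mesh <- profile_to_mesh(pr, width = 2)
  sec <- extract_cross_section(mesh, 0, site_id = "ribbon")
  # every original point appears on the extracted section
  d <- vapply(seq_len(nrow(pr$section$points)), function(i)
    min(sqrt(rowSums(sweep(sec$points, 2,
                           pr$section$points[i, ])^2))), 1)
  expect_lt(max(d), 1e-6)
})

test_that("measured depth is invariant to rigid motion of mesh and frame", {
  pr <- generate_profile(profile_spec(crown_span = 1.5, gingiva_span = 0.5))
  mesh <- profile_to_mesh(pr, width = 2)
  depth_of <- function(m, frame) {
    m2 <- apply_frame(m, frame)
    sec <- extract_cross_section(m2, 0)
    det <- detect_landmarks(run_pipeline(sec))
    recession_depth(det$cej, det$gm)
  }
  d0 <- depth_of(mesh, local_frame())
  set.seed(8)
  ax <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  t0 <- rnorm(3, 0, 10)
  # world vertices v' = v R + t; the frame with axes = rows of R undoes it
  moved <- dental_mesh(mesh$vertices %*% ax + matrix(t0, nrow(mesh$vertices),
                                                     3, byrow = TRUE),
                       mesh$faces)
  fr <- local_frame(origin = t0, x_axis = ax[1, ], z_axis = ax[3, ],
                    y_axis = ax[2, ])
  d1 <- depth_of(moved, fr)
  expect_lt(abs(d1 - d0), 1e-6)
})

test_that("refinement does not move the landmarks", {
  pr <- generate_profile(profile_spec(crown_span = 1.2, gingiva_span = 0.5),
                         step = 0.05)
  mesh <- profile_to_mesh(pr, width = 0.4)
  # mesh sections are chorded polygons: fit with the default smoothing
  # bound rather than interpolating through the kinks
  det_of <- function(m) {
    sec <- extract_cross_section(m, 0)
    det <- detect_landmarks(run_pipeline(sec, smoothing = 0.005))
    c(det$cej$s, det$gm$s)
  }
  base <- det_of(mesh)
  refined <- det_of(refine_mesh(mesh, 0.2, max_passes = 4))
  expect_lt(max(abs(base - refined)), 0.01 + 1e-9)
})
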