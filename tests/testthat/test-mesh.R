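test_that("STL round-trips: binary and ASCII dialects give the same mesh", {
  m <- cube_mesh()
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, fb, binary = TRUE)
  write_stl(m, fa, binary = FALSE)
  mb <- read_mesh(fb)
  ma <- read_mesh(fa)
  expect_equal(nrow(ma$vertices), 8L)   # cube merges back to 8 vertices
  expect_equal(nrow(ma$faces), 12L)
  expect_equal(nrow(mb$vertices), nrow(ma$vertices))
  expect_equal(nrow(mb$faces), nrow(ma$faces))
  # same vertex sets after merging (order-independent)
  ord <- function(v) v[do.call(order, as.data.frame(v)), ]
  expect_equal(ord(mb$vertices), ord(ma$vertices), tolerance = 1e-6)
})

test_that("read_mesh handles a minimal binary STL and rejects bad files", {
  tri <- dental_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(tri, f, binary = TRUE)
  m <- read_mesh(f)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)

  expect_error(read_mesh(file.path(tempdir(), "nope.stl")), "not found")
  # truncated binary: claims 5 facets, contains 1
  f2 <- withr::local_tempfile(fileext = ".stl")
  con <- file(f2, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4L, endian = "little")
  writeBin(numeric(12), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mesh(f2), "truncated")
  # zero faces
  f3 <- withr::local_tempfile(fileext = ".stl")
  con <- file(f3, "wb")
  writeBin(raw(80), con)
  writeBin(0L, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mesh(f3), "empty mesh")
})

test_that("mesh invariants are enforced", {
  expect_error(dental_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(dental_mesh(diag(3), rbind(c(1, 2, 2))), "repeated")
  expect_error(dental_mesh(diag(3), matrix(0L, 0L, 3L)), "empty mesh")
})

test_that("refine_mesh shortens edges, preserves area, and is idempotent", {
  tri <- dental_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0.8, 0)),
                     rbind(c(1, 2, 3)))
  r <- refine_mesh(tri, 0.6)
  expect_lte(max_edge_len(r), 0.6)
  expect_equal(mesh_area(r), mesh_area(tri), tolerance = 1e-12)

  again <- refine_mesh(r, 0.6)
  expect_equal(nrow(again$faces), nrow(r$faces))
  expect_equal(nrow(again$vertices), nrow(r$vertices))

  cube <- cube_mesh()
  rc <- refine_mesh(cube, 0.25)
  expect_lte(max_edge_len(rc), 0.25)
  expect_equal(mesh_area(rc), 6, tolerance = 1e-9)
  expect_error(refine_mesh(cube, -1), "positive")
})

test_that("apply_frame is rigid and validates the frame", {
  m <- cube_mesh()
  expect_equal(apply_frame(m, local_frame())$vertices, m$vertices)

  shifted <- apply_frame(m, local_frame(origin = c(1, 2, 3)))
  expect_equal(shifted$vertices, sweep(m$vertices, 2, c(1, 2, 3)))

  # random rigid frame preserves all pairwise distances
  set.seed(42)
  ax <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  fr <- local_frame(origin = rnorm(3), x_axis = ax[, 1],
                    z_axis = ax[, 3], y_axis = ax[, 2])
  m2 <- apply_frame(m, fr)
  expect_equal(as.numeric(dist(m2$vertices)), as.numeric(dist(m$vertices)),
               tolerance = 1e-9)

  expect_error(local_frame(x_axis = c(1, 0, 0), z_axis = c(1, 0, 0)),
               "orthogonal|unit")
  expect_error(local_frame(x_axis = c(2, 0, 0)), "unit")
})

test_that("cube cross-section is a closed square of perimeter 4", {
  m <- cube_mesh()
  sec <- extract_cross_section(m, 0.5, buccal_side = FALSE)
  expect_true(sec$closed)
  p <- sec$points
  per <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2))) +
    sqrt(sum((p[1, ] - p[nrow(p), ])^2))   # close the loop
  expect_equal(per, 4, tolerance = 1e-9)
  # every section point lies on the cube surface (section fidelity)
  on_surface <- apply(p, 1L, function(q)
    any(abs(q - 0) < 1e-9 | abs(q - 1) < 1e-9))
  expect_true(all(on_surface))
})

test_that("buccal-side restriction keeps the larger-mean-y sub-chain", {
  m <- cube_mesh()
  sec <- extract_cross_section(m, 0.5, buccal_side = TRUE)
  expect_gte(mean(sec$points[, 1]), 0.5)
  # ordering coronal -> apical
  expect_gte(sec$points[1, 2], sec$points[nrow(sec$points), 2])
})

test_that("sphere cross-section perimeter converges to 2*pi*r", {
  r <- 5
  m <- sphere_mesh(r = r, n_lat = 40, n_lon = 80)
  sec <- extract_cross_section(m, 0, buccal_side = FALSE)
  p <- sec$points
  per <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2))) +
    sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  expect_equal(per, 2 * pi * r, tolerance = 0.005 * 2 * pi * r)
})

test_that("plane outside the mesh raises a no-intersection error", {
  expect_error(extract_cross_section(cube_mesh(), 5), "no intersection")
})

test_that("polyline CSV round-trips through write/read", {
  pr <- generate_profile(profile_spec(crown_span = 1.5, gingiva_span = 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_polyline(pr$section, f)
  back <- read_polyline(f, site_id = "rt")
  expect_equal(back$points, pr$section$points, tolerance = 1e-12)
  # plain 2-column whitespace dialect
  f2 <- withr::local_tempfile(fileext = ".txt")
  write.table(pr$section$points, f2, row.names = FALSE, col.names = FALSE)
  back2 <- read_polyline(f2)
  expect_equal(back2$points, pr$section$points, tolerance = 1e-6)
})

test_that("the shipped synthetic ribbon fixture runs end to end", {
  stl <- system.file("extdata", "synthetic_tooth_ribbon.stl",
                     package = "gingrec")
  m <- read_mesh(stl)
  sec <- extract_cross_section(m, 0, site_id = "demo")
  det <- detect_landmarks(run_pipeline(sec, smoothing = 0.005))
  # fixture is deliberately coarse (0.15 mm chords); depth is approximate
  expect_equal(recession_depth(det$cej, det$gm), 1.9, tolerance = 0.05)
})
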