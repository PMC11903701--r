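test_that("heron_area matches classic cases and the cross-product oracle", {
  expect_equal(heron_area(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)), 6)
  expect_equal(heron_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
  set.seed(7)
  p1 <- matrix(rnorm(150), 50, 3)
  p2 <- matrix(rnorm(150), 50, 3)
  p3 <- matrix(rnorm(150), 50, 3)
  # independent oracle: half the cross-product magnitude of two edges
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  oracle <- 0.5 * sqrt(rowSums(cr^2))
  expect_equal(heron_area(p1, p2, p3), oracle, tolerance = 1e-12)
})

test_that("heron_area stays finite and tiny for needle triangles", {
  a <- c(0, 0, 0); b <- c(1, 0, 0)
  cvec <- c(0.5, 1e-13, 0)
  got <- heron_area(a, b, cvec)
  expect_gte(got, 0)
  expect_equal(got, 0.5 * 1e-13, tolerance = 1e-6)
})

test_that("newell_plane recovers known normals and follows rotations", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 5)  # CCW square in z = 5
  pl <- newell_plane(sq)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-14)
  expect_equal(pl$center, c(0.5, 0.5, 5))
  # clockwise orientation flips the sign
  expect_equal(newell_plane(sq[4:1, ])$normal, c(0, 0, -1), tolerance = 1e-14)
  # rotating the polygon rotates the normal identically
  R <- axis_rotation("x", pi / 4)
  pl_rot <- newell_plane(sq %*% t(R))
  expect_equal(pl_rot$normal, as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-12)
  # degenerate inputs
  expect_error(newell_plane(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
               "degenerate")
  expect_error(newell_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "degenerate")
})

test_that("projection_area is exact for planar polygons in any orientation", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)  # unit square, 1 m side
  for (s in 1:4) {
    R <- random_rotation(20 + s)
    moved <- sweep(sq %*% t(R), 2, rnorm(3), `+`)
    expect_equal(as.numeric(projection_area(moved)), 1e4, tolerance = 1e-9)
  }
  # concave L-shape: 1 x 1 square minus a 0.5 x 0.5 corner = 0.75 m^2
  L <- cbind(c(0, 1, 1, 0.5, 0.5, 0), c(0, 0, 0.5, 0.5, 1, 1), 2)
  R <- axis_rotation("y", 0.7)
  expect_equal(as.numeric(projection_area(L %*% t(R))), 7500, tolerance = 1e-9)
})

test_that("self-intersecting contours are flagged but still measured", {
  # one crossing edge pair, nonzero net signed area
  poly <- cbind(c(0, 3, 3, 1, 0), c(0, 0, 2, -1, 2), 0)
  expect_warning(a <- projection_area(poly), "self-intersecting")
  expect_true(attr(a, "self_intersecting"))
  expect_gt(as.numeric(a), 0)
})

test_that("label_components separates 4-connected blobs", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[7:9, 6:9] <- TRUE
  m[5, 5] <- TRUE  # diagonal touch only: its own component
  lab <- label_components(m)
  expect_equal(max(lab), 3)
  expect_equal(sum(lab > 0), sum(m))
  expect_length(unique(lab[m][lab[m] > 0]), 3)
})

test_that("trace_boundary walks the outer contour in order", {
  m <- matrix(FALSE, 8, 9)
  m[3:6, 3:6] <- TRUE
  b <- trace_boundary(m)
  expect_equal(nrow(b), 12)  # 4x4 block has 12 boundary cells
  # consecutive boundary pixels are 8-adjacent, closed cyclically
  d <- pmax(abs(diff(rbind(b, b[1, ]))[, 1]), abs(diff(rbind(b, b[1, ]))[, 2]))
  expect_true(all(d == 1))
  expect_setequal(paste(b[, 1], b[, 2]),
                  paste(rep(3:6, times = 4), rep(3:6, each = 4))[
                    !(rep(3:6, times = 4) %in% 4:5 & rep(3:6, each = 4) %in% 4:5)])
  # single-row component degenerates to its own pixels
  m2 <- matrix(FALSE, 5, 5); m2[3, 2:4] <- TRUE
  expect_equal(nrow(trace_boundary(m2)), 4)  # there and back, minus repeats
  expect_error(trace_boundary(matrix(FALSE, 3, 3)), "empty")
})

test_that("surface_area_3d reproduces flat and curved reference areas", {
  # flat constant-depth rectangle: area = a x b pixel extents
  sc <- flat_scene(H = 64, W = 64, depth = 0.5, fx = 200, fy = 200,
                   mask_fun = function(u, v) u >= 10 & u <= 49 & v >= 20 & v <= 39)
  g <- unproject_depth_map(sc$depth, sc$mask, sc$K)
  out <- surface_area_3d(g)
  px <- 0.5 / 200  # metric pixel pitch at this depth
  expect_equal(out$area_cm2, (39 * px) * (19 * px) * 1e4, tolerance = 1e-9)
  expect_equal(out$coverage, 1)
  # flat-surface identity: triangulated area equals the contour's
  # projection area (the masked extent is a simple rectangle)
  bnd <- trace_boundary(g$valid)
  pts <- cbind(g$x[bnd], g$y[bnd], g$z[bnd])
  expect_equal(out$area_cm2, as.numeric(projection_area(pts)), tolerance = 1e-9)

  # quarter-cylinder patch: analytic area R * theta * L
  qc <- quarter_cylinder_grid(R = 0.1, L = 0.2, H = 192, W = 256)
  a_qc <- surface_area_3d(qc)$area_cm2
  expect_equal(a_qc, 0.1 * (pi / 2) * 0.2 * 1e4, tolerance = 5e-3)

  # spherical cap: analytic area 2 pi R^2 (1 - cos theta)
  cap <- spherical_cap_grid(R = 0.1, theta = pi / 6, H = 256, W = 512)
  a_cap <- surface_area_3d(cap)$area_cm2
  expect_equal(a_cap, 2 * pi * 0.1^2 * (1 - cos(pi / 6)) * 1e4, tolerance = 5e-3)
})

test_that("the quad-splitting diagonal is immaterial", {
  qc <- quarter_cylinder_grid(R = 0.1, L = 0.2, H = 96, W = 128)
  a1 <- surface_area_3d(qc, diagonal = "tlbr")$area_cm2
  a2 <- surface_area_3d(qc, diagonal = "trbl")$area_cm2
  analytic <- 0.1 * (pi / 2) * 0.2 * 1e4
  expect_lt(abs(a1 - a2), abs(a1 - analytic))  # below discretization error
})

test_that("triangles require all three vertices valid and masked", {
  sc <- flat_scene(H = 8, W = 8, depth = 1, fx = 100, fy = 100)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  d <- sc$depth; d[4, 4] <- NA  # knock out the central pixel
  g <- unproject_depth_map(d, mask, sc$K)
  out <- surface_area_3d(g)
  # 3x3 masked block has 4 quads = 8 triangles; the center vertex is in
  # every quad, killing 6 of them (one triangle per quad avoids the center
  # in 2 quads)
  expect_equal(out$triangle_count, 2L)
  expect_equal(out$coverage, 0)
  full <- surface_area_3d(unproject_depth_map(sc$depth, mask, sc$K))
  expect_equal(full$triangle_count, 8L)
  expect_equal(full$coverage, 1)
  # nothing measurable at all
  mask2 <- matrix(FALSE, 8, 8); mask2[1, 1] <- TRUE
  expect_error(surface_area_3d(unproject_depth_map(sc$depth, mask2, sc$K)),
               "unmeasurable")
})

test_that("measure_wounds handles flat scenes, multi-wound additivity and errors", {
  disc1 <- function(u, v) (u - 40)^2 + (v - 47)^2 < 20^2
  disc2 <- function(u, v) (u - 90)^2 + (v - 47)^2 < 14^2
  sc <- flat_scene(H = 96, W = 128, depth = 0.3, fx = 400, fy = 400)
  m1 <- disc1(matrix(rep(0:127, each = 96), 96, 128),
              matrix(rep(0:95, times = 128), 96, 128))
  m2 <- disc2(matrix(rep(0:127, each = 96), 96, 128),
              matrix(rep(0:95, times = 128), 96, 128))
  r1 <- measure_wounds(sc$depth, m1, sc$K)
  expect_s3_class(r1, "wound_measurement")
  expect_equal(nrow(r1), 1)
  r2 <- measure_wounds(sc$depth, m2, sc$K)
  both <- measure_wounds(sc$depth, m1 | m2, sc$K)
  expect_equal(nrow(both), 2)
  g <- glance(both)
  # additivity: totals equal the sums of single-wound runs
  expect_equal(g$area2d_cm2, r1$area2d_cm2 + r2$area2d_cm2, tolerance = 1e-9)
  expect_equal(g$area3d_cm2, r1$area3d_cm2 + r2$area3d_cm2, tolerance = 1e-9)
  expect_error(measure_wounds(sc$depth, m1 & m2, sc$K), "no wound")
})

test_that("flat surfaces give a 3D/2D ratio within 0.5% at native scale", {
  # disc about 140 px across, comparable to the rendered template scenes
  sc <- flat_scene(H = 192, W = 256, depth = 0.3, fx = 600, fy = 600,
                   mask_fun = function(u, v) (u - 127)^2 + (v - 95)^2 < 70^2)
  r <- measure_wounds(sc$depth, sc$mask, sc$K)
  expect_equal(r$ratio, 1, tolerance = 5e-3)
  expect_equal(r$coverage, 1)
})

test_that("low depth coverage raises a flag", {
  sc <- flat_scene(H = 48, W = 48, depth = 0.5, fx = 300, fy = 300)
  mask <- matrix(FALSE, 48, 48); mask[10:40, 10:40] <- TRUE
  d <- sc$depth
  set.seed(3)
  holes <- sample(which(mask), 200)
  d[holes] <- NA
  expect_warning(r <- measure_wounds(d, mask, sc$K), "coverage")
  expect_true(any(r$low_coverage))
  expect_lt(min(r$coverage), 0.95)
})

test_that("areas are invariant under rigid motion of the camera frame", {
  sc <- flat_scene(H = 64, W = 64, depth = 0.4, fx = 300, fy = 300,
                   mask_fun = function(u, v) (u - 32)^2 + (v - 32)^2 < 22^2)
  base <- measure_wounds(sc$depth, sc$mask, sc$K)
  for (s in 1:3) {
    ext <- camera_extrinsics(random_rotation(30 + s), rnorm(3) * 0.2)
    moved <- measure_wounds(sc$depth, sc$mask, sc$K, ext)
    # same depths and mask expressed in a different world frame: identical
    # areas up to floating-point rotation noise
    expect_equal(moved$area2d_cm2, base$area2d_cm2, tolerance = 1e-9)
    expect_equal(moved$area3d_cm2, base$area3d_cm2, tolerance = 1e-9)
  }
})
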