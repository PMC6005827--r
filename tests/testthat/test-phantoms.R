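test_that("straight tube intensity model is exact at voxel centres", {
  dx <- 0.25
  ph <- straight_tube_phantom(c(32, 32, 16), rep(dx, 3), radius = 2,
                              I_lumen = 1000, I_bg = 0, wall_width = 0)
  ctr <- ph$truth$params$center
  # on-axis voxel -> lumen value; 2R off axis -> background
  i_on <- round(ctr[1:2] / dx + 0.5)
  expect_equal(ph$volume$data[i_on[1], i_on[2], 8], 1000)
  # corner voxel is well over 2R from the axis
  expect_equal(ph$volume$data[1, 1, 8], 0)
})

test_that("hard-threshold segmentation reproduces the analytic predicate", {
  dx <- 0.25
  dims <- c(32, 32, 12)
  ph <- straight_tube_phantom(dims, rep(dx, 3), radius = 2, wall_width = 0)
  pts <- hemovox:::grid_points(dims, rep(dx, 3))
  expect_identical(as.vector(ph$volume$data > 500),
                   as.vector(ph$truth$inside(pts)))
})

test_that("voxel count of a noise-free tube matches the analytic volume", {
  dx <- 0.25
  dims <- c(32, 32, 20)
  ph <- straight_tube_phantom(dims, rep(dx, 3), radius = 10 * dx)
  n <- sum(ph$volume$data > 500)
  expect_equal(n * dx^3, ph$truth$volume_mm3, tolerance = 0.02)
})

test_that("phantoms are deterministic given a seed", {
  a <- straight_tube_phantom(c(16, 16, 8), rep(0.3, 3), radius = 1,
                             noise_sd = 50, seed = 42)
  b <- straight_tube_phantom(c(16, 16, 8), rep(0.3, 3), radius = 1,
                             noise_sd = 50, seed = 42)
  c <- straight_tube_phantom(c(16, 16, 8), rep(0.3, 3), radius = 1,
                             noise_sd = 50, seed = 43)
  expect_identical(a$volume$data, b$volume$data)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("phantom preconditions are enforced", {
  expect_error(straight_tube_phantom(c(16, 16, 8), rep(0.3, 3), radius = 0.5),
               "at least 3 voxels")
  expect_error(curved_tube_phantom(c(16, 16, 8), rep(0.3, 3),
                                   torus_major_R = 1, tube_radius = 1.2,
                                   arc_span = 45), "exceed")
})

test_that("curved tube centerline points are at full lumen intensity", {
  ph <- curved_tube_phantom(c(40, 24, 40), rep(0.25, 3), torus_major_R = 6,
                            tube_radius = 1.2, arc_span = 90)
  for (th in c(-0.6, 0, 0.4)) {
    p <- matrix(ph$truth$centerline_point(th), 1)
    expect_equal(ph$truth$sdist(p), 1.2, tolerance = 1e-12)
  }
})

test_that("curved tube signed distance matches a brute-force surface search", {
  ph <- curved_tube_phantom(c(40, 24, 40), rep(0.25, 3), torus_major_R = 6,
                            tube_radius = 1.2, arc_span = 90)
  tr <- ph$truth
  C <- tr$params$arc_center
  Rm <- tr$params$torus_major_R
  half <- pi / 4
  th <- seq(-half, half, length.out = 20001)
  arcs <- cbind(C[1] - Rm * cos(th), C[2] + 0 * th, C[3] + Rm * sin(th))
  tt <- seq(0, 20, length.out = 40001)
  T_lo <- c(sin(-half), 0, cos(-half))
  T_hi <- c(sin(half), 0, cos(half))
  ray1 <- t(vapply(tt, function(s) arcs[1, ] - s * T_lo, numeric(3)))
  ray2 <- t(vapply(tt, function(s) arcs[nrow(arcs), ] + s * T_hi, numeric(3)))
  allpts <- rbind(arcs, ray1, ray2)
  set.seed(7)
  pts <- cbind(runif(40, 1, 9), runif(40, 1, 5), runif(40, 1, 9))
  bf <- apply(pts, 1, function(p)
    1.2 - min(sqrt(colSums((t(allpts) - p)^2))))
  expect_lt(max(abs(tr$sdist(pts) - bf)), 1e-6)
})

test_that("arc span 0 degenerates to the straight tube", {
  a <- curved_tube_phantom(c(24, 24, 20), rep(0.25, 3), torus_major_R = 6,
                           tube_radius = 1, arc_span = 0)
  b <- straight_tube_phantom(c(24, 24, 20), rep(0.25, 3), radius = 1)
  expect_equal(a$volume$data, b$volume$data)
})

test_that("sidewall aneurysm union is monotone and volumetrically consistent", {
  dx <- 0.25
  dims <- c(56, 36, 32)
  ph <- sidewall_aneurysm_phantom(dims, rep(dx, 3), radius = 2.5)
  tube <- straight_tube_phantom(dims, rep(dx, 3), radius = 2.5)
  # sac centre is inside the lumen
  expect_true(ph$truth$inside(matrix(ph$truth$params$sac_center, 1)))
  n_union <- sum(ph$volume$data > 500)
  n_tube <- sum(tube$volume$data > 500)
  expect_gte(n_union, n_tube)
  # sphere + cylinder - cap closed form, 3% at R = 10 voxels
  expect_equal(n_union * dx^3, ph$truth$volume_mm3, tolerance = 0.03)
})

test_that("disjoint sac placement is rejected", {
  expect_error(
    sidewall_aneurysm_phantom(c(40, 32, 32), rep(0.25, 3), radius = 2.5,
                              sac_center = c(9.5, 4, 4), sac_radius = 1),
    "disconnected")
})

test_that("two-vessel phantom components are disjoint and sized correctly", {
  dx <- 0.25
  dims <- c(56, 28, 16)
  ph <- two_vessel_phantom(dims, rep(dx, 3), radius1 = 2.5, radius2 = 2.0)
  pts <- hemovox:::grid_points(dims, rep(dx, 3))
  comp <- ph$truth$component(pts)
  bright <- as.vector(ph$volume$data > 500)
  expect_identical(bright, comp > 0L)       # counts partition the lumen
  L <- dims[3] * dx
  expect_equal(sum(comp == 1L) * dx^3, pi * 2.5^2 * L, tolerance = 0.02)
  expect_equal(sum(comp == 2L) * dx^3, pi * 2.0^2 * L, tolerance = 0.02)
  expect_error(two_vessel_phantom(dims, rep(dx, 3), radius1 = 2.5,
                                  radius2 = 2, separation = 4), "overlap")
})
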