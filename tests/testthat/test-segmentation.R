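test_that("region growing follows the threshold criterion", {
  # a bright path and a bright-but-disconnected voxel
  I <- array(0, c(5, 5, 5))
  I[3, 3, 3] <- 700          # seed
  I[4, 3, 3] <- 600          # face neighbor above threshold -> included
  I[2, 3, 3] <- 400          # below threshold -> excluded
  I[1, 1, 1] <- 900          # bright but disconnected -> cleaned up
  v <- intensity_volume(I, rep(0.25, 3))
  m <- region_grow(v, c(3, 3, 3), I0 = 500)
  expect_true(m$mask[3, 3, 3])
  expect_true(m$mask[4, 3, 3])
  expect_false(m$mask[2, 3, 3])
  expect_false(m$mask[1, 1, 1])
  expect_equal(sum(m$mask), 2L)
})

test_that("a seed surrounded by dark voxels stays a single-voxel mask", {
  I <- array(0, c(5, 5, 5)); I[3, 3, 3] <- 700
  m <- region_grow(intensity_volume(I, rep(0.25, 3)), c(3, 3, 3), 500)
  expect_equal(which(m$mask), which(I == 700))
})

test_that("seed below threshold is an error", {
  I <- array(0, c(4, 4, 4))
  expect_error(region_grow(intensity_volume(I, rep(1, 3)), c(2, 2, 2), 500),
               "seed intensity")
})

test_that("region growing equals the breadth-first oracle on noisy phantoms", {
  for (s in 1:6) {
    ph <- straight_tube_phantom(c(12, 12, 10), rep(0.4, 3),
                                radius = 1.2 + 0.1 * s,
                                axis = if (s %% 2) "z" else "x",
                                wall_width = 0.4, noise_sd = 120, seed = s)
    I <- ph$volume$data
    seedv <- c(6, 6, 5)
    if (I[6, 6, 5] <= 500) next
    m <- region_grow(ph$volume, seedv, 500)
    expect_identical(m$mask, bfs_oracle(I, seedv, 500))
    # with the gradient criterion as well
    m2 <- region_grow(ph$volume, seedv, 500, grad_max = 300)
    expect_identical(m2$mask, bfs_oracle(I, seedv, 500, grad_max = 300))
  }
})

test_that("the unseeded vessel is cleaned up entirely", {
  ph <- two_vessel_phantom(c(40, 20, 12), rep(0.25, 3), radius1 = 1.5,
                           radius2 = 1.2)
  tr <- ph$truth
  seedv <- round(c(tr$params$center1[1:2] / 0.25 + 0.5), 0)
  m <- region_grow(ph$volume, c(seedv, 6), 500)
  pts <- hemovox:::grid_points(ph$volume$dims, rep(0.25, 3))
  comp <- array(tr$component(pts), ph$volume$dims)
  expect_equal(sum(m$mask & comp == 2L), 0L)
  expect_equal(sum(m$mask), sum(comp == 1L))
})

test_that("lowering the threshold never shrinks the mask", {
  ph <- straight_tube_phantom(c(16, 16, 12), rep(0.3, 3), radius = 1.4,
                              wall_width = 0.6, noise_sd = 80, seed = 9)
  m1 <- region_grow(ph$volume, c(8, 8, 6), 520)
  m2 <- region_grow(ph$volume, c(8, 8, 6), 430)
  expect_true(all(m2$mask[m1$mask]))
})

test_that("every masked voxel is face-connected to the seed", {
  ph <- sidewall_aneurysm_phantom(c(30, 22, 20), rep(0.3, 3), radius = 1.5,
                                  wall_width = 0.3, noise_sd = 60, seed = 3)
  m <- region_grow(ph$volume, c(15, 11, 10), 500)
  refl <- bfs_oracle(ifelse(m$mask, 1000, 0), m$seed, 500)
  expect_identical(m$mask, refl)
})

test_that("tube spanning z yields exactly two opposite openings", {
  ph <- straight_tube_phantom(c(20, 20, 16), rep(0.3, 3), radius = 1.5)
  m <- region_grow(ph$volume, c(10, 10, 8), 500)
  pat <- identify_openings(m, "kmin")
  expect_length(pat, 2)
  expect_setequal(vapply(pat, function(p) p$face, ""), c("kmin", "kmax"))
  roles <- vapply(pat, function(p) p$role, "")
  expect_equal(sum(roles == "inflow"), 1L)
  # centroid of the circular opening is the tube centre to half a voxel
  ctr <- ph$truth$params$center
  infl <- pat[[which(roles == "inflow")]]
  expect_lt(max(abs(infl$centroid_mm[1:2] - ctr[1:2])), 0.15)
  expect_error(identify_openings(m, "imin"), "no masked voxels")
})

test_that("a branching vessel yields one inflow and two outflows", {
  dx <- 0.3
  dims <- c(30, 20, 30)
  main <- straight_tube_phantom(dims, rep(dx, 3), radius = 1.2)
  ctr <- main$truth$params$center
  pts <- hemovox:::grid_points(dims, rep(dx, 3))
  sd_branch <- hemovox:::sd_tube(pts, ctr,
                                 hemovox:::normalize(c(1, 0, 1)), 1.0)
  I <- pmax(main$volume$data, array(1000 * (sd_branch > 0), dims))
  v <- intensity_volume(I, rep(dx, 3))
  m <- region_grow(v, c(15, 10, 15), 500)
  # the branch also crosses the inflow face, so the largest patch is taken
  expect_warning(pat <- identify_openings(m, "kmin"), "largest")
  roles <- vapply(pat, function(p) p$role, "")
  expect_equal(sum(roles == "inflow"), 1L)
  expect_gte(sum(roles == "outflow"), 2L)
  faces <- vapply(pat, function(p) p$face, "")
  expect_true("imax" %in% faces)
})
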