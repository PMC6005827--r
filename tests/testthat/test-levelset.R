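test_that("the raw level set is the thresholded intensity", {
  I <- array(600, c(4, 4, 4))
  ls <- build_levelset(intensity_volume(I, rep(1, 3)), 500)
  expect_equal(ls$phi0, array(100, c(4, 4, 4)))
  v2 <- intensity_volume(array(runif(64, 300, 800), c(4, 4, 4)), rep(1, 3))
  ls2 <- build_levelset(v2, 500)
  expect_equal(range(ls2$phi0), range(v2$data) - 500)
  ls3 <- build_levelset(intensity_volume(array(500, c(4, 4, 4)), rep(1, 3)),
                        500)
  expect_true(all(ls3$phi0 == 0))
})

test_that("the 27-point filter has the printed weights and unit sum", {
  # unit impulse at the centre of a 5^3 block
  I <- array(0, c(5, 5, 5)); I[3, 3, 3] <- 1
  ls <- smooth_levelset(build_levelset(intensity_volume(I, rep(1, 3)), 0))
  expect_equal(ls$phi[3, 3, 3], 1 / 8)    # centre (1/2)^3
  expect_equal(ls$phi[4, 3, 3], 1 / 16)   # face neighbor
  expect_equal(ls$phi[4, 4, 3], 1 / 32)   # edge neighbor
  expect_equal(ls$phi[4, 4, 4], 1 / 64)   # corner neighbor
  expect_equal(sum(ls$phi), 1)            # weights sum to exactly 1
})

test_that("a constant field is a fixed point of the filter, even at edges", {
  I <- array(7.25, c(6, 5, 4))
  ls <- smooth_levelset(build_levelset(intensity_volume(I, rep(1, 3)), 0))
  expect_equal(ls$phi, I)
})

test_that("the filter is linear and diffuses toward a constant", {
  a <- array(rnorm(6^3), c(6, 6, 6))
  b <- array(rnorm(6^3), c(6, 6, 6))
  sm <- function(x) {
    ls <- build_levelset(intensity_volume(x + 1000, rep(1, 3)), 1000)
    smooth_levelset(ls)$phi
  }
  expect_equal(sm(2 * a + 3 * b), 2 * sm(a) + 3 * sm(b))
  x <- a
  for (i in 1:60) x <- sm(x)
  expect_lt(diff(range(x)), 0.05 * diff(range(a)))
})

test_that("wall distances are exact for an affine level set", {
  # phi = a*(x - x_w): d_x is the true signed distance, other axes absent
  nx <- 8; dx <- 0.5
  xw <- 1.3
  xs <- (seq_len(nx) - 0.5) * dx
  phi <- array(rep(2 * (xs - xw), times = 64), c(nx, 8, 8))
  ls <- synthetic_levelset(phi, rep(dx, 3))
  mask <- synthetic_mask(phi > 0, rep(dx, 3))
  wg <- wall_distances(ls, mask)
  xcell <- (as.numeric(wg$cells[, 1]) - 0.5) * dx
  ok <- !is.na(wg$d[, 1])
  expect_equal(wg$d[ok, 1], xcell[ok] - xw, tolerance = 1e-12)
  # direct substitution: phi = 1, dphi/dx = 2 / mm -> d = 0.5 mm
  expect_equal(1 / 2, 0.5)
  some <- !is.na(wg$d[, 1])
  expect_true(any(some))
  expect_true(all(is.na(wg$d[, 2])))   # no gradient in y
})

test_that("sub-voxel wall recovery on a spherical level set converges at second order", {
  err_at <- function(dx) {
    n <- round(8 / dx)
    xs <- (seq_len(n) - 0.5) * dx
    ctr <- c(4.03, 4.07, 4.11)
    R <- 2.5
    dist <- sqrt(outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`),
                       (xs - ctr[3])^2, `+`))
    phi <- R - dist
    ls <- synthetic_levelset(phi, rep(dx, 3))
    mask <- synthetic_mask(phi > 0, rep(dx, 3))
    wg <- wall_distances(ls, mask)
    errs <- c()
    for (ax in 1:3) {
      ok <- which(!is.na(wg$d[, ax]))
      pw <- sweep(wg$cells[ok, , drop = FALSE] - 0.5, 2, rep(dx, 3), `*`)
      pw[, ax] <- pw[, ax] - wg$d[ok, ax]
      rw <- sqrt(rowSums(sweep(pw, 2, ctr)^2))
      errs <- c(errs, abs(rw - R))
    }
    mean(errs)
  }
  e1 <- err_at(0.4)
  e2 <- err_at(0.2)
  expect_gt(log2(e1 / e2), 1.5)
})

test_that("tube phantom wall radius is recovered to sub-voxel accuracy", {
  dx <- 0.25; R <- 2.0
  ph <- straight_tube_phantom(c(26, 26, 20), rep(dx, 3), radius = R,
                              wall_width = 2 * dx)
  ctr <- ph$truth$params$center
  m <- region_grow(ph$volume, c(13, 13, 10), 500)
  ls <- smooth_levelset(build_levelset(ph$volume, 500))
  wg <- wall_distances(ls, m)
  cc <- sweep(wg$cells - 0.5, 2, rep(dx, 3), `*`)
  errs <- c()
  for (ax in 1:2) {
    ok <- !is.na(wg$d[, ax]) & wg$cells[, 3] > 2 & wg$cells[, 3] < 19
    pw <- cc[ok, , drop = FALSE]
    pw[, ax] <- pw[, ax] - wg$d[ok, ax]
    rw <- sqrt((pw[, 1] - ctr[1])^2 + (pw[, 2] - ctr[2])^2)
    errs <- c(errs, abs(rw - R))
  }
  expect_lt(max(errs), 0.5 * dx)
})

test_that("wall normals are unit length and geometrically correct", {
  # planar field phi = x
  nx <- 6; dx <- 1
  xs <- (seq_len(nx) - 0.5) * dx
  phi <- array(rep(xs, times = 36), c(nx, 6, 6))
  ls <- synthetic_levelset(phi, rep(dx, 3))
  nrm <- wall_normals(ls)
  expect_equal(max(abs(nrm[, , , 1] - 1)), 0)
  expect_equal(max(abs(nrm[, , , 2:3])), 0)
  # spherical field: normals antiparallel to the radius vector
  n <- 16
  xs <- (seq_len(n) - 0.5) * 0.5
  ctr <- c(4.1, 4.2, 3.9)
  dist <- sqrt(outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`),
                     (xs - ctr[3])^2, `+`))
  ls2 <- synthetic_levelset(2.5 - dist, rep(0.5, 3))
  set.seed(1)
  cells <- cbind(sample(2:15, 30, TRUE), sample(2:15, 30, TRUE),
                 sample(2:15, 30, TRUE))
  cells <- cells[sqrt(rowSums(sweep(sweep(cells - 0.5, 2, rep(0.5, 3), `*`),
                                    2, ctr)^2)) > 1.5, , drop = FALSE]
  nr <- wall_normals(ls2, cells)
  expect_equal(rowSums(nr^2), rep(1, nrow(nr)), tolerance = 1e-12)
  rv <- sweep(sweep(cells - 0.5, 2, rep(0.5, 3), `*`), 2, ctr)
  rv <- rv / sqrt(rowSums(rv^2))
  # central differences of the distance field carry O(dx^2) lattice
  # anisotropy; direction agreement is tested to that level
  expect_lt(max(abs(nr + rv)), 0.03)
})
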