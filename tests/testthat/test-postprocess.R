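
test_that("wall pressure is the adjacent cell pressure", {
  ss <- shear_state()
  wg <- wall_distances(ss$ls, ss$mask)
  ss$state$P[] <- 137.5
  expect_true(all(wall_pressure(ss$state, wg) == 137.5))
  # pressure varying tangentially to the wall is picked up exactly
  for (k in 1:6) ss$state$P[, , k] <- k * 10
  wp <- wall_pressure(ss$state, wg)
  expect_equal(wp, wg$cells[, 3] * 10)
})

test_that("a linear shear field gives exact near-wall gradients and WSS", {
  ss <- shear_state(gamma = 400)
  wg <- wall_distances(ss$ls, ss$mask)
  grad <- near_wall_gradient(ss$state, wg)
  # du/dy = gamma * 1e-3 / 1e-3 ... u in m/s with y in m: gradient = gamma/s
  expect_equal(max(abs(grad[, 1, 2] - ss$gamma * 1)), 0, tolerance = 1e-9)
  # all other tensor entries vanish
  expect_lt(max(abs(grad[, , c(1, 3)])), 1e-9)
  expect_lt(max(abs(grad[, 2:3, ])), 1e-9)
  # plane shear: u = (gamma y, 0, 0), n = (0, 1, 0) -> tau = (mu gamma, 0, 0)
  wf <- wall_shear_stress(grad, wg, mu = 0.0035)
  expect_equal(wf$tau[, 1], rep(0.0035 * ss$gamma, nrow(wf$tau)),
               tolerance = 1e-9)
  expect_lt(max(abs(wf$tau[, 2:3])), 1e-12)
})

test_that("sub-grid wall offsets keep the linear-shear gradient exact", {
  ss <- shear_state(gamma = 250, yw = 1.3 * 0.5)   # wall 0.3 dx above the face
  wg <- wall_distances(ss$ls, ss$mask)
  grad <- near_wall_gradient(ss$state, wg)
  expect_equal(max(abs(grad[, 1, 2] - 250)), 0, tolerance = 1e-9)
})

test_that("a purely wall-normal gradient produces zero WSS", {
  ss <- shear_state()
  wg <- wall_distances(ss$ls, ss$mask)
  n <- nrow(wg$cells)
  grad <- array(0, c(n, 3, 3))
  grad[, 2, 2] <- 123    # dv/dy: normal component varying along the normal
  wf <- wall_shear_stress(grad, wg, 0.0035)
  expect_lt(max(wf$tau_mag), 1e-12)
})

test_that("WSS is tangential to the wall on the Poiseuille run", {
  run <- pois10()
  grad <- near_wall_gradient(run$state, run$wallgeom)
  wf <- wall_shear_stress(grad, run$wallgeom, run$mu)
  resid <- abs(rowSums(wf$tau * run$wallgeom$normals))
  expect_lt(max(resid / pmax(wf$tau_mag, 1e-300)), 1e-10)
})

test_that("mean Poiseuille WSS and axial pressure gradient match theory", {
  run <- pois10()
  grad <- near_wall_gradient(run$state, run$wallgeom)
  wf <- wall_shear_stress(grad, run$wallgeom, run$mu)
  d <- run$dims
  sel <- run$wallgeom$cells[, 3] > round(d[3] * 0.2) &
    run$wallgeom$cells[, 3] < round(d[3] * 0.8)
  expect_equal(mean(wf$tau_mag[sel]), 2 * run$mu * run$U0 / (run$R * 1e-3),
               tolerance = 0.10)
  wp <- wall_pressure(run$state, run$wallgeom)
  zz <- (run$wallgeom$cells[sel, 3] - 0.5) * run$dx * 1e-3
  slope <- stats::coef(stats::lm(wp[sel] ~ zz))[[2]]
  expect_equal(slope, -4 * run$mu * run$U0 / (run$R * 1e-3)^2,
               tolerance = 0.05)
})

test_that("metric arithmetic matches the hand computation", {
  # wall values {1, 2, 3} Pa with rho U0^2 = 1 Pa
  cells <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  wf <- structure(list(cells = cells, tau = cbind(1:3, 0, 0),
                       tau_mag = c(1, 2, 3),
                       normals = cbind(0, 1, 0)[rep(1, 3), ]),
                  class = "wall_field")
  d <- c(6, 6, 6)
  state <- structure(list(
    U = array(0, d + c(1, 0, 0)), V = array(0, d + c(0, 1, 0)),
    W = array(0, d + c(0, 0, 1)), P = array(0, d), dims = d,
    h = rep(1e-3, 3), spacing = rep(1, 3)), class = "flow_state")
  region <- array(FALSE, d); region[2:4, 2, 2] <- TRUE
  met <- aneurysm_metrics(wf, state, region, U0 = 1, rho = 1)
  expect_equal(met$tau_star_max, 3)
  expect_equal(met$tau_star_avg, 2)
  expect_equal(met$tau_star_var, sqrt(2 / 3))
  expect_equal(met$vel_ratio_avg, 0)     # zero-flow state
})

test_that("size ratio follows its definition", {
  # 6 mm sac on a 4 mm parent: two cell centres 6 mm apart
  mask <- synthetic_mask(array(TRUE, c(8, 8, 8)), rep(1, 3))
  region <- rbind(c(1, 1, 1), c(7, 1, 1))   # centres at 0.5 and 6.5 mm
  expect_equal(size_ratio(region, mask, parent_diameter = 4), 1.5)
  # single-voxel region has (near) zero extent
  expect_equal(size_ratio(rbind(c(2, 2, 2)), mask, parent_diameter = 4), 0)
  expect_error(size_ratio(region, mask, parent_diameter = 0), "degenerate")
})

test_that("phantom sidewall SR is close to the analytic sac/tube ratio", {
  dx <- 0.3
  ph <- sidewall_aneurysm_phantom(c(42, 24, 24), rep(dx, 3), radius = 8 * dx,
                                  sac_radius = 7 * dx)
  m <- region_grow(ph$volume, c(18, 12, 12), 500)
  infl <- Filter(function(p) p$role == "inflow",
                 identify_openings(m, "kmin"))[[1]]
  fr <- inplane_radius(vessel_centerline(m, infl))
  region <- aneurysm_region_from_truth(m, ph$truth)
  sr <- size_ratio(region, m, fr)
  # maximal sac chord is about the sac diameter; parent diameter 2 R_tube
  expect_equal(sr, (2 * 7 * dx) / (2 * 8 * dx), tolerance = 0.1)
})

test_that("metrics are invariant under cell reordering and tau* scales as 1/U0
           in the Stokes regime", {
  # viscosity chosen so both runs sit deep in the Stokes regime (Re << 1);
  # a common fixed dt keeps the discrete operators identical so the check
  # probes the U0 scaling alone
  runA <- fixture("stokes_a", poiseuille_run(6, U0 = 0.05, mu = 0.7,
                                             R = 2.4, length_cells = 12L,
                                             dt = 5e-4))
  runB <- fixture("stokes_b", poiseuille_run(6, U0 = 0.10, mu = 0.7,
                                             R = 2.4, length_cells = 12L,
                                             dt = 5e-4))
  star <- function(run) {
    grad <- near_wall_gradient(run$state, run$wallgeom)
    wf <- wall_shear_stress(grad, run$wallgeom, run$mu)
    sel <- run$wallgeom$cells[, 3] > 3 & run$wallgeom$cells[, 3] < 10
    mean(wf$tau_mag[sel]) / (1060 * run$U0^2)
  }
  sA <- star(runA); sB <- star(runB)
  expect_equal(sB / sA, 0.5, tolerance = 0.02)
  # reordering the wall cells leaves the metrics unchanged
  run <- runA
  grad <- near_wall_gradient(run$state, run$wallgeom)
  wf <- wall_shear_stress(grad, run$wallgeom, run$mu)
  region <- array(FALSE, run$dims)
  region[run$mask$mask] <- TRUE
  m1 <- aneurysm_metrics(wf, run$state, region, run$U0)
  perm <- rev(seq_len(nrow(wf$cells)))
  wf2 <- wf
  wf2$cells <- wf$cells[perm, ]
  wf2$tau <- wf$tau[perm, ]
  wf2$tau_mag <- wf$tau_mag[perm]
  m2 <- aneurysm_metrics(wf2, run$state, region, run$U0)
  expect_equal(m1, m2)
})
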