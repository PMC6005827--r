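# Heavier verification of the flow solver against analytic solutions. The
# voxelized-tube Poiseuille runs are shared, cached fixtures (see
# helper-fixtures.R).

test_that("zero state with zero boundary data stays zero in the predictor", {
  cs <- channel_setup()
  solver <- solver_setup(cs$mask, cs$ls, list(), NULL, cs$cfg)
  solver <- solver_factorize(solver, dt = 1e-4)
  state <- list(u = lapply(solver$comps, function(cm) numeric(cm$n_dof)),
                conv_prev = NULL, t = 0)
  pred <- momentum_predictor(solver, state)
  expect_equal(max(abs(unlist(pred$ustar))), 0)
})

test_that("uniform velocity in a fully periodic box is unchanged", {
  arr <- array(TRUE, c(6, 6, 6))
  mask <- synthetic_mask(arr, rep(0.5, 3))
  cfg <- solver_config(rho = 1000, mu = 0.01, periodic = rep(TRUE, 3),
                       max_time = 1)
  solver <- solver_setup(mask, NULL, list(), NULL, cfg)
  solver <- solver_factorize(solver, dt = 1e-3)
  u0 <- lapply(solver$comps, function(cm) rep(0.37, cm$n_dof))
  state <- list(u = u0, conv_prev = NULL, t = 0)
  pred <- momentum_predictor(solver, state)
  for (m in 1:3)
    expect_equal(pred$ustar[[m]], u0[[m]], tolerance = 1e-12)
})

test_that("viscous decay of a sine mode between offset walls matches theory", {
  cs <- channel_setup(ny = 34)
  solver <- solver_setup(cs$mask, cs$ls, list(), NULL, cs$cfg)
  nu <- cs$cfg$mu / cs$cfg$rho
  dt <- 0.25 * (cs$dx * 1e-3)^2 / nu     # diffusive CFL 0.25
  solver <- solver_factorize(solver, dt)
  cm <- solver$comps[[1]]
  H <- (cs$yw2 - cs$yw1) * 1e-3
  yc <- (cm$dof_coord[, 2] - 1 - 0.5) * cs$dx * 1e-3
  u0 <- sin(pi * (yc - cs$yw1 * 1e-3) / H)
  state <- list(u = list(u0, numeric(solver$comps[[2]]$n_dof),
                         numeric(solver$comps[[3]]$n_dof)),
                conv_prev = NULL, t = 0)
  for (s in 1:200) {
    pred <- momentum_predictor(solver, state)
    state$u <- pred$ustar
    state$conv_prev <- pred$conv
    state$t <- state$t + dt
  }
  decay <- max(abs(state$u[[1]])) / max(abs(u0))
  expect_equal(decay, exp(-nu * pi^2 / H^2 * state$t), tolerance = 0.005)
})

test_that("the assembled Poisson operator is second-order on a cosine mode", {
  n <- 24; dx <- 0.5e-3
  arr <- array(TRUE, c(n, 4, 4))
  mask <- synthetic_mask(arr, rep(dx * 1e3, 3))
  cfg <- solver_config(rho = 1000, mu = 0.01, periodic = rep(TRUE, 3),
                       max_time = 1)
  solver <- solver_setup(mask, NULL, list(), NULL, cfg)
  L <- n * dx
  k <- 2 * pi / L
  xs <- (solver$cells[, 1] - 0.5) * dx
  p <- cos(k * xs)
  lap <- -as.numeric(solver$A_p %*% p)     # A_p is the negative Laplacian
  # discrete symbol error is (k dx)^2 / 12 relative
  expect_lt(max(abs(lap + k^2 * p)) / k^2, (k * dx)^2 / 6)
})

test_that("an all-Neumann pressure system is reported as singular", {
  cs <- channel_setup()
  solver <- solver_setup(cs$mask, cs$ls, list(), NULL, cs$cfg)
  solver$dt <- 1e-4
  expect_error(pressure_poisson(solver, numeric(solver$n_cell)),
               "all-Neumann")
})

test_that("zero pressure leaves the corrector a no-op, and the projection
           contract holds on the Poiseuille run", {
  run <- pois10()
  dg <- run$state$diagnostics
  # discrete incompressibility after every step
  expect_lt(max(dg$max_div), 1e-8)
  # global mass conservation after flux rescaling: recompute from the state
  d <- run$dims
  area <- (run$dx * 1e-3)^2
  flux_in <- sum(run$state$W[, , 1]) * area
  flux_out <- sum(run$state$W[, , d[3] + 1]) * area
  expect_lt(abs(flux_out / flux_in - 1), 1e-10)
  # CFL stayed bounded and was recorded
  expect_true(all(dg$cfl <= 1.2))
})

test_that("steady voxelized-tube flow reproduces Poiseuille", {
  run <- pois10()
  d <- run$dims
  wc <- cell_velocity(run$state)$w[, , round(d[3] / 2)]
  xs <- (seq_len(d[1]) - 0.5) * run$dx
  ys <- (seq_len(d[2]) - 0.5) * run$dx
  r2 <- outer(xs - run$center[1], ys - run$center[2],
              function(a, b) a^2 + b^2)
  ana <- run$U0 * pmax(0, 1 - r2 / run$R^2)
  ins <- run$mask$mask[, , round(d[3] / 2)]
  expect_lt(max(abs(wc - ana)[ins]) / run$U0, 0.05)
})

test_that("plane channel flow with sub-grid wall offsets matches the parabola", {
  cs <- channel_setup(ny = 16, nz = 24, dx = 0.4, off1 = 0.3, off2 = 0.3,
                      periodic = c(TRUE, FALSE, FALSE), mu = 0.04)
  mask <- cs$mask
  pat <- identify_openings(mask, "kmin")
  pat <- Filter(function(p) p$axis == 3L, pat)
  infl <- Filter(function(p) p$role == "inflow", pat)[[1]]
  fr <- vessel_centerline(mask, infl, depth = 2)
  U0 <- 0.3
  yc <- (cs$yw1 + cs$yw2) / 2
  hh <- (cs$yw2 - cs$yw1) / 2
  yv <- (infl$voxels[, 2] - 0.5) * cs$dx
  uz <- U0 * pmax(0, 1 - ((yv - yc) / hh)^2)
  prof <- structure(list(frame = fr, U0 = U0, steady = TRUE,
                         velocity = function(t = 0) cbind(0, 0, uz)),
                    class = "inflow_profile")
  cfg <- solver_config(mu = 0.04, periodic = c(TRUE, FALSE, FALSE),
                       max_time = 3, steady_tol = 1e-6)
  solver <- suppressWarnings(solver_setup(mask, cs$ls, pat, prof, cfg))
  state <- run_solver(solver)
  ys <- (seq_len(16) - 0.5) * cs$dx
  wz <- cell_velocity(state)$w[2, , 12]
  ana <- U0 * pmax(0, 1 - ((ys - yc) / hh)^2)
  expect_lt(max(abs(wz - ana)[mask$mask[2, , 1]]) / U0, 0.03)
})

test_that("the solver is deterministic across repeated runs", {
  a <- poiseuille_run(6, R = 2.4, length_cells = 12L, steady_tol = 1e-4)
  b <- poiseuille_run(6, R = 2.4, length_cells = 12L, steady_tol = 1e-4)
  expect_identical(a$state$U, b$state$U)
  expect_identical(a$state$P, b$state$P)
})
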