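# Shared fixtures. Heavy solver runs are computed once per test session and
# cached, so several test files (and the acceptance checks) can share them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# ---- reference flood fill (independent oracle for region growing) ----------
# deliberately naive: repeated full-array dilation until a fixed point
bfs_oracle <- function(I, seed, I0, grad_max = NULL) {
  d <- dim(I)
  inmask <- array(FALSE, d)
  inmask[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grew <- FALSE
    idx <- which(inmask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + s
        if (q[ax] < 1L || q[ax] > d[ax]) next
        if (inmask[q[1], q[2], q[3]]) next
        if (I[q[1], q[2], q[3]] <= I0) next
        if (!is.null(grad_max) &&
            abs(I[q[1], q[2], q[3]] - I[p[1], p[2], p[3]]) >= grad_max) next
        inmask[q[1], q[2], q[3]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  inmask
}

# ---- independent Bessel/Womersley oracle (quadrature, not the series) ------
J0_quad <- function(z) {
  gl <- pracma::gaussLegendre(96, 0, pi)
  vapply(z, function(zz) as.complex(sum(gl$w * cos(zz * sin(gl$x))) / pi),
         complex(1))
}

womersley_shape_oracle <- function(xi, Wo) {
  a <- complex(modulus = 1, argument = 3 * pi / 4) * Wo
  (1 - J0_quad(a * xi) / J0_quad(a)) / (1 - 1 / J0_quad(a))
}

# ---- synthetic grids for solver unit tests ---------------------------------
synthetic_mask <- function(arr, spacing) {
  structure(list(mask = arr, seed = NULL, I0 = NA, grad_max = NULL,
                 spacing = spacing, origin = c(0, 0, 0), dims = dim(arr)),
            class = "lumen_mask")
}

synthetic_levelset <- function(phi, spacing) {
  structure(list(phi0 = phi, phi = phi, I0 = 0, spacing = spacing,
                 origin = c(0, 0, 0), dims = dim(phi), smoothed = TRUE),
            class = "levelset_field")
}

# plane channel bounded in y (solid layers j = 1 and j = ny), walls placed
# off1/off2 voxel fractions inside the faces of the solid layers
channel_setup <- function(ny = 18, nx = 4, nz = 4, dx = 0.5,
                          off1 = 0.3, off2 = 0.7, periodic = c(TRUE, FALSE, TRUE),
                          rho = 1000, mu = 1) {
  arr <- array(TRUE, c(nx, ny, nz)); arr[, 1, ] <- FALSE; arr[, ny, ] <- FALSE
  mask <- synthetic_mask(arr, rep(dx, 3))
  yw1 <- (1.5 - off1) * dx
  yw2 <- ((ny - 0.5) - off2) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  phi1 <- pmin(ys - yw1, yw2 - ys)
  phi <- array(rep(rep(phi1, each = nx), nz), c(nx, ny, nz))
  ls <- synthetic_levelset(phi, rep(dx, 3))
  cfg <- solver_config(rho = rho, mu = mu, periodic = periodic, max_time = 10)
  list(mask = mask, ls = ls, cfg = cfg, yw1 = yw1, yw2 = yw2, dx = dx)
}

# ---- voxelized straight-tube Poiseuille run (shared heavy fixture) ---------
poiseuille_run <- function(ncell_r, U0 = 0.5, mu = 0.035, R = NULL,
                           length_cells = NULL, steady_tol = 1e-6,
                           dt = NULL) {
  if (is.null(R)) R <- 2.5
  dx <- R / ncell_r
  nxy <- as.integer(2 * ncell_r + 6)
  nz <- if (is.null(length_cells)) as.integer(4 * ncell_r + 4) else length_cells
  dims <- c(nxy, nxy, nz)
  ph <- straight_tube_phantom(dims, rep(dx, 3), radius = R,
                              wall_width = 2 * dx)
  ctr <- ph$truth$params$center
  m <- region_grow(ph$volume, c(round(nxy / 2), round(nxy / 2), round(nz / 2)),
                   I0 = 500)
  pat <- identify_openings(m, "kmin")
  ls <- smooth_levelset(build_levelset(ph$volume, 500))
  infl <- Filter(function(p) p$role == "inflow", pat)[[1]]
  fr <- inplane_radius(vessel_centerline(m, infl))
  prof <- parabolic_profile(fr, U0)
  cfg <- solver_config(mu = mu, max_time = 2, steady_tol = steady_tol,
                       dt = dt)
  solver <- solver_setup(m, ls, pat, prof, cfg)
  state <- run_solver(solver)
  wg <- wall_distances(ls, m)
  list(state = state, mask = m, ls = ls, wallgeom = wg, frame = fr,
       profile = prof, patches = pat, center = ctr, R = R, dx = dx,
       dims = dims, U0 = U0, mu = mu)
}

pois10 <- function() fixture("pois10", poiseuille_run(10))
pois6 <- function() fixture("pois6", poiseuille_run(6, R = 2.4,
                                                    length_cells = 20L))
pois12 <- function() fixture("pois12", poiseuille_run(12, R = 2.4,
                                                      length_cells = 40L))

# L2 error of the axial velocity against the analytic Poiseuille profile,
# over the mid 40% of the tube length
poiseuille_l2 <- function(run) {
  d <- run$dims
  wc <- cell_velocity(run$state)$w
  xs <- (seq_len(d[1]) - 0.5) * run$dx
  ys <- (seq_len(d[2]) - 0.5) * run$dx
  r2 <- outer(xs - run$center[1], ys - run$center[2],
              function(a, b) a^2 + b^2)
  ana <- run$U0 * pmax(0, 1 - r2 / run$R^2)
  ks <- round(d[3] * 0.3):round(d[3] * 0.7)
  err2 <- 0; n <- 0
  for (k in ks) {
    ins <- run$mask$mask[, , k]
    err2 <- err2 + sum((wc[, , k][ins] - ana[ins])^2)
    n <- n + sum(ins)
  }
  sqrt(err2 / n) / run$U0
}

# sidewall-aneurysm pipeline config used by the end-to-end tests
sidewall_cfg <- function(out_dir) {
  pipeline_config(
    phantom = list(kind = "sidewall_aneurysm", dims = c(30, 22, 24),
                   spacing = rep(0.3, 3), radius = 1.5, sac_radius = 1.2),
    seed = c(15, 11, 12), I0 = 500, inflow_face = "kmin", U0 = 0.3,
    mu = 0.035, max_time = 1, steady_tol = 1e-4, output_dir = out_dir)
}

# hand-made plane-shear flow state for post-processing exactness checks
shear_state <- function(gamma = 400, ny = 10, dx = 0.5, yw = NULL) {
  nx <- 6; nz <- 6
  if (is.null(yw)) yw <- 1.0 * dx          # wall at the j=1/j=2 cell face
  arr <- array(TRUE, c(nx, ny, nz)); arr[, 1, ] <- FALSE
  mask <- synthetic_mask(arr, rep(dx, 3))
  ys <- (seq_len(ny) - 0.5) * dx
  phi <- array(rep(rep(ys - yw, each = nx), nz), c(nx, ny, nz))
  ls <- synthetic_levelset(phi, rep(dx, 3))
  # u = gamma * (y - yw), v = w = 0; staggered U sampled at cell-centre y
  U <- array(rep(rep(pmax(gamma * (ys - yw) * 1e-3, -Inf), each = nx + 1), nz),
             c(nx + 1, ny, nz))
  state <- structure(list(
    U = U, V = array(0, c(nx, ny + 1, nz)), W = array(0, c(nx, ny, nz + 1)),
    P = array(0, c(nx, ny, nz)), t = 0, dt = 1, steps = 0,
    converged = "steady", diagnostics = data.frame(),
    dims = c(nx, ny, nz), h = rep(dx * 1e-3, 3), spacing = rep(dx, 3),
    mask = mask), class = "flow_state")
  list(state = state, mask = mask, ls = ls, gamma = gamma, yw = yw)
}
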