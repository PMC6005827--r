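# Operator assembly and time stepping for the immersed-boundary solver.
# Everything here works on the structures produced by solver_setup(): per
# component, `u` is the vector of interior (DOF) face velocities and the full
# padded face arrays are reconstructed on demand from u plus the ghost chains.

build_poisson <- function(solver, memb_role) {
  d <- solver$dims
  h <- solver$h
  cells <- solver$cells
  n <- solver$n_cell
  cb <- solver$cell_id_big
  db <- dim(cb)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag_acc <- numeric(n)
  pc <- cells + 2L                       # halo coords
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- pc
    nb[, ax] <- nb[, ax] + s
    nid <- cb[lin3(nb, db)]
    has <- nid > 0L
    diag_acc[has] <- diag_acc[has] + 1 / h[ax]^2
    ti <- c(ti, which(has)); tj <- c(tj, nid[has])
    tx <- c(tx, rep(-1 / h[ax]^2, sum(has)))
  }
  # Dirichlet P = 0 on outflow boundary faces
  n_outflow <- 0L
  for (fn in names(memb_role)) {
    sp <- face_specs(d)[[fn]]
    sel <- which(memb_role[[fn]] == "outflow", arr.ind = TRUE)
    if (nrow(sel) == 0) next
    ids <- solver$cell_id[sel]
    diag_acc[ids] <- diag_acc[ids] + 2 / h[sp$axis]^2
    n_outflow <- n_outflow + nrow(sel)
  }
  ti <- c(ti, seq_len(n)); tj <- c(tj, seq_len(n)); tx <- c(tx, diag_acc)
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  A <- Matrix::forceSymmetric(A)
  solver$poisson_singular <- n_outflow == 0L
  solver$A_p <- A
  if (!solver$poisson_singular)
    solver$chol_p <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  # divergence gather indices: padded face positions of each cell's 6 faces
  divL <- divR <- vector("list", 3)
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    fL <- cells; fR <- cells
    fR[, m] <- fR[, m] + 1L              # unpadded face indices
    divL[[m]] <- lin3(fL + 1L, cm$P)
    divR[[m]] <- lin3(fR + 1L, cm$P)
  }
  solver$divL <- divL; solver$divR <- divR
  solver
}

build_momentum <- function(solver) {
  h <- solver$h
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    n <- cm$n_dof
    pos <- cm$pos_dof
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    gi <- integer(0); gj <- integer(0); gx <- numeric(0)
    diag_acc <- rep(-2 * sum(1 / h^2), n)
    npad <- prod(cm$P)
    nbidx <- matrix(0L, n, 6)
    for (ax in 1:3) for (si in 1:2) {
      s <- c(-1L, 1L)[si]
      p2 <- pos + s * cm$st[ax]
      nbidx[, (ax - 1) * 2 + si] <- p2
      nd <- cm$dof_id[p2]
      ng <- cm$ghost_id[p2]
      hasd <- nd > 0L
      hasg <- ng > 0L
      ti <- c(ti, which(hasd)); tj <- c(tj, nd[hasd])
      tx <- c(tx, rep(1 / h[ax]^2, sum(hasd)))
      gi <- c(gi, which(hasg)); gj <- c(gj, ng[hasg])
      gx <- c(gx, rep(1 / h[ax]^2, sum(hasg)))
    }
    ti <- c(ti, seq_len(n)); tj <- c(tj, seq_len(n)); tx <- c(tx, diag_acc)
    A_ff <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
    Bg <- Matrix::sparseMatrix(i = gi, j = gj, x = gx,
                               dims = c(n, max(cm$n_ghost, 1L)))
    cm$A_L <- A_ff + Bg %*% cm$C
    cm$Bg <- Bg
    cm$nbidx <- nbidx
    # transverse advecting-velocity gather indices (4 per other component)
    adv <- vector("list", 3)
    pc <- cm$dof_coord
    for (nn in setdiff(1:3, m)) {
      cn <- solver$comps[[nn]]
      q <- matrix(0L, n, 4)
      kk <- 1L
      for (dn in 0:1) for (dm in c(-1L, 0L)) {
        cc <- pc
        cc[, nn] <- cc[, nn] + dn
        cc[, m] <- cc[, m] + dm
        q[, kk] <- lin3(cc, cn$P)
        kk <- kk + 1L
      }
      adv[[nn]] <- q
    }
    cm$adv <- adv
    # pressure-correction cell ids
    cbig <- solver$cell_id_big
    dbig <- dim(cbig)
    # halo cell coords flanking each DOF face: axis m -> p[m], p[m]+1
    cl <- cbind(pc[, 1] + 1L, pc[, 2] + 1L, pc[, 3] + 1L)
    cl[, m] <- pc[, m]
    cr <- cl; cr[, m] <- cl[, m] + 1L
    cm$cidL <- cbig[lin3(cl, dbig)]
    cm$cidR <- cbig[lin3(cr, dbig)]
    # outflow face bookkeeping
    if (length(cm$outflow_slot)) {
      gc <- cm$ghost_pos[cm$outflow_slot]
      co <- arr_coord(gc, cm$P)
      f <- co - 1L
      cellm <- ifelse(cm$outflow_sign < 0, f[, m], f[, m] - 1L)
      cellco <- f
      cellco[, m] <- cellm
      cm$outflow_cid <- solver$cell_id[cellco]
      cm$outflow_pos <- gc
      cm$outflow_area <- prod(h[-m])
    } else {
      cm$outflow_cid <- integer(0)
      cm$outflow_pos <- integer(0)
      cm$outflow_area <- prod(h[-m])
    }
    if (length(cm$infl_norm_slot)) {
      cm$infl_norm_pos <- cm$ghost_pos[cm$infl_norm_slot]
      gc <- arr_coord(cm$infl_norm_pos, cm$P)
      cm$infl_norm_sign <- ifelse(gc[, m] == 2L, 1, -1) # min face: inward = +
    } else {
      cm$infl_norm_pos <- integer(0)
      cm$infl_norm_sign <- numeric(0)
    }
    solver$comps[[m]] <- cm
  }
  solver
}

arr_coord <- function(pos, dd) {
  p0 <- pos - 1L
  cbind(p0 %% dd[1] + 1L,
        (p0 %/% dd[1]) %% dd[2] + 1L,
        p0 %/% (dd[1] * dd[2]) + 1L)
}

# ghost-chain constant part at time t (inflow profile values)
solver_g0 <- function(solver, t = 0) {
  prof <- solver$profile
  vel <- if (is.null(prof)) NULL else prof$velocity(t)
  lapply(1:3, function(m) {
    cm <- solver$comps[[m]]
    g0 <- cm$g0_static
    if (!is.null(vel)) {
      if (length(cm$infl_norm_slot))
        g0[cm$infl_norm_slot] <- vel[cm$infl_norm_row, m]
      if (length(cm$infl_tan_slot))
        g0[cm$infl_tan_slot] <- 2 * vapply(
          cm$infl_tan_rows, function(r)
            if (length(r)) mean(vel[r, m]) else 0, numeric(1))
    }
    g0
  })
}

# reconstruct the full padded face arrays from the interior unknowns
fill_faces <- function(solver, u, g0) {
  lapply(1:3, function(m) {
    cm <- solver$comps[[m]]
    full <- numeric(prod(cm$P))
    full[cm$pos_dof] <- u[[m]]
    if (cm$n_ghost > 0)
      full[cm$ghost_pos] <- as.numeric(cm$C %*% u[[m]]) + g0[[m]]
    full
  })
}

# advective term (u . grad) u_m at the DOF faces of each component
convection <- function(solver, full) {
  h <- solver$h
  lapply(1:3, function(m) {
    cm <- solver$comps[[m]]
    fm <- full[[m]]
    conv <- numeric(cm$n_dof)
    own <- fm[cm$pos_dof]
    for (ax in 1:3) {
      dudx <- (fm[cm$nbidx[, (ax - 1) * 2 + 2]] -
                 fm[cm$nbidx[, (ax - 1) * 2 + 1]]) / (2 * h[ax])
      vadv <- if (ax == m) own else {
        q <- cm$adv[[ax]]
        fn <- full[[ax]]
        0.25 * (fn[q[, 1]] + fn[q[, 2]] + fn[q[, 3]] + fn[q[, 4]])
      }
      conv <- conv + vadv * dudx
    }
    conv
  })
}

#' Advance the momentum equation to the intermediate velocity
#'
#' One predictor step of the fractional-step scheme: explicit Adams-Bashforth
#' 2 convection (forward Euler on the first step) and Crank-Nicolson viscous
#' terms, with the ghost-fluid wall closures folded into the implicit
#' operator. The pressure gradient is absent by construction; the projection
#' restores incompressibility afterwards.
#'
#' @param solver a `flow_solver` (see [solver_setup()]) with factorized
#'   operators (created by [run_solver()] or [solver_factorize()]).
#' @param state solver state list with `u` (list of 3 DOF vectors),
#'   `conv_prev`, `t`.
#' @return list with `ustar` (DOF vectors), `conv` (for the next AB2 step),
#'   `full` (padded face arrays of the input state), `cfl` (measured).
#' @export
momentum_predictor <- function(solver, state) {
  cfg <- solver$config
  dt <- solver$dt
  nu <- cfg$mu / cfg$rho
  g0 <- solver_g0(solver, state$t)
  g0n <- if (!is.null(solver$profile) && !isTRUE(solver$profile$steady))
    solver_g0(solver, state$t + dt) else g0
  full <- fill_faces(solver, state$u, g0)
  conv <- convection(solver, full)
  cfl <- max(vapply(1:3, function(m) {
    cm <- solver$comps[[m]]
    umax <- if (cm$n_dof > 0) max(abs(state$u[[m]])) else 0
    if (length(cm$infl_norm_slot))
      umax <- max(umax, abs(g0[[m]][cm$infl_norm_slot]))
    umax * dt / solver$h[m]
  }, numeric(1)))
  if (cfl > 1.2)
    stop(sprintf("CFL violation: measured CFL = %.3g (dt too large)", cfl))
  ustar <- vector("list", 3)
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    if (cm$n_dof == 0) { ustar[[m]] <- numeric(0); next }
    b_n <- as.numeric(cm$Bg %*% g0[[m]])
    b_np <- as.numeric(cm$Bg %*% g0n[[m]])
    cexp <- if (is.null(state$conv_prev))
      conv[[m]] else 1.5 * conv[[m]] - 0.5 * state$conv_prev[[m]]
    rhs <- state$u[[m]] / dt - cexp +
      (nu / 2) * (as.numeric(cm$A_L %*% state$u[[m]]) + b_n + b_np)
    ustar[[m]] <- as.numeric(Matrix::solve(cm$M1_lu, rhs))
  }
  list(ustar = ustar, conv = conv, full = full, cfl = cfl, g0 = g0n)
}

# cell divergence of a set of full face arrays (1/s)
divergence <- function(solver, full) {
  d <- numeric(solver$n_cell)
  for (m in 1:3) {
    d <- d + (full[[m]][solver$divR[[m]]] - full[[m]][solver$divL[[m]]]) /
      solver$h[m]
  }
  d
}

#' Solve the pressure Poisson equation
#'
#' `lap(P) = (rho/dt) div(u*)` over the fluid cells, with homogeneous Neumann
#' conditions at walls and inflow and `P = 0` on outflow boundary faces. The
#' constant operator is factorized once (sparse Cholesky) and re-used, so the
#' projection is exact to round-off.
#'
#' @param solver a `flow_solver`.
#' @param div cell divergence of the intermediate velocity (1/s).
#' @return pressure vector over fluid cells (Pa).
#' @export
pressure_poisson <- function(solver, div) {
  if (isTRUE(solver$poisson_singular))
    stop("pressure system is all-Neumann (no outflow patch): singular")
  rhs <- -(solver$config$rho / solver$dt) * div
  as.numeric(Matrix::solve(solver$chol_p, rhs, system = "A"))
}

#' Project the intermediate velocity to a divergence-free field
#'
#' Subtracts the pressure gradient on interior faces and on outflow boundary
#' faces (consistently with the Dirichlet pressure condition there), then
#' rescales the outflow face velocities by one global factor so the total
#' outflow flux equals the total inflow flux.
#'
#' @param solver a `flow_solver`.
#' @param pred output of [momentum_predictor()].
#' @param P pressure vector from [pressure_poisson()].
#' @return list with `u` (corrected DOF vectors), `full` (corrected full
#'   arrays, outflow rescaled), `flux_in`, `flux_out`, `alpha` (rescale
#'   factor), `max_div` (post-projection, before rescaling).
#' @export
corrector <- function(solver, pred, P) {
  cfg <- solver$config
  dtorho <- solver$dt / cfg$rho
  u <- vector("list", 3)
  full <- fill_faces(solver, pred$ustar, pred$g0)
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    if (cm$n_dof == 0) { u[[m]] <- numeric(0); next }
    gradP <- (P[cm$cidR] - P[cm$cidL]) / solver$h[m]
    u[[m]] <- pred$ustar[[m]] - dtorho * gradP
    full[[m]][cm$pos_dof] <- u[[m]]
    if (length(cm$outflow_pos)) {
      corr <- dtorho * cm$outflow_sign * 2 * P[cm$outflow_cid] / solver$h[m]
      full[[m]][cm$outflow_pos] <- full[[m]][cm$outflow_pos] + corr
    }
  }
  md <- max(abs(divergence(solver, full)))
  flux_in <- 0; flux_out <- 0
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    if (length(cm$infl_norm_pos))
      flux_in <- flux_in + sum(full[[m]][cm$infl_norm_pos] *
                                 cm$infl_norm_sign) * prod(solver$h[-m])
    if (length(cm$outflow_pos))
      flux_out <- flux_out + sum(full[[m]][cm$outflow_pos] *
                                   cm$outflow_sign) * cm$outflow_area
  }
  alpha <- if (flux_out != 0) flux_in / flux_out else 1
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    if (length(cm$outflow_pos))
      full[[m]][cm$outflow_pos] <- full[[m]][cm$outflow_pos] * alpha
  }
  list(u = u, full = full, flux_in = flux_in, flux_out = flux_out,
       alpha = alpha, max_div = md)
}

#' Factorize the time-stepping operators
#'
#' Chooses the time step (from the CFL target and the peak inflow speed when
#' not fixed) and computes the sparse LU factorization of the Crank-Nicolson
#' momentum matrices. Called automatically by [run_solver()].
#'
#' @param solver a `flow_solver`.
#' @param dt optional explicit time step (s), overriding the config.
#' @return the solver with `dt` and factorizations attached.
#' @export
solver_factorize <- function(solver, dt = NULL) {
  cfg <- solver$config
  if (is.null(dt)) dt <- cfg$dt
  if (is.null(dt)) {
    uref <- if (!is.null(solver$profile))
      max(abs(solver$profile$velocity(0))) else 0
    if (uref <= 0)
      stop("cannot choose dt automatically without an inflow profile; set dt")
    dt <- cfg$cfl * min(solver$h) / uref
  }
  solver$dt <- dt
  nu <- cfg$mu / cfg$rho
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    if (cm$n_dof == 0) next
    M1 <- Matrix::Diagonal(cm$n_dof, 1 / dt) - (nu / 2) * cm$A_L
    cm$M1_lu <- Matrix::lu(M1)
    solver$comps[[m]] <- cm
  }
  solver
}

#' Run the immersed-boundary flow simulation
#'
#' Advances the fractional-step scheme until the configured end time, the
#' step cap, or a steady state (relative L2 velocity change per flow-through
#' time below `steady_tol`). Fully deterministic for fixed inputs.
#'
#' @param solver a `flow_solver` from [solver_setup()].
#' @param init optional initial DOF velocity vectors (list of 3); zero start
#'   by default.
#' @param dt optional time step override (s).
#' @return A `flow_state`: unpadded staggered face arrays `U`, `V`, `W`
#'   (m/s), cell pressure array `P` (Pa), `t`, `dt`, `steps`, `converged`
#'   ("steady", "max_time" or "max_steps") and a per-step `diagnostics` data
#'   frame (`t`, `max_div`, `cfl`, `rel_change`, `alpha`, `flux_in`,
#'   `flux_out`).
#' @export
run_solver <- function(solver, init = NULL, dt = NULL) {
  cfg <- solver$config
  if (is.null(solver$dt) || !is.null(dt) || is.null(solver$comps[[1]]$M1_lu))
    solver <- solver_factorize(solver, dt)
  u <- if (is.null(init)) lapply(solver$comps, function(cm) numeric(cm$n_dof))
  else init
  state <- list(u = u, conv_prev = NULL, t = 0)
  uref <- if (!is.null(solver$profile))
    max(abs(solver$profile$velocity(0))) else NULL
  Tflow <- if (!is.null(uref) && uref > 0)
    max(solver$dims * solver$h) / uref else 1
  diag_rows <- list()
  converged <- "max_steps"
  nstep <- 0L
  last <- NULL
  while (nstep < cfg$max_steps) {
    nstep <- nstep + 1L
    pred <- momentum_predictor(solver, state)
    div_star <- divergence(solver, fill_faces(solver, pred$ustar, pred$g0))
    P <- pressure_poisson(solver, div_star)
    corr <- corrector(solver, pred, P)
    du <- sqrt(sum(vapply(1:3, function(m)
      sum((corr$u[[m]] - state$u[[m]])^2), numeric(1))))
    un <- sqrt(sum(vapply(1:3, function(m)
      sum(corr$u[[m]]^2), numeric(1))))
    rel <- if (un > 0) du / un else du
    state$u <- corr$u
    state$conv_prev <- pred$conv
    state$t <- state$t + solver$dt
    diag_rows[[nstep]] <- c(t = state$t, max_div = corr$max_div,
                            cfl = pred$cfl, rel_change = rel,
                            alpha = corr$alpha, flux_in = corr$flux_in,
                            flux_out = corr$flux_out)
    if (cfg$verbose && nstep %% 50L == 0L)
      message(sprintf("step %d t=%.4g div=%.3g cfl=%.3g rel=%.3g",
                      nstep, state$t, corr$max_div, pred$cfl, rel))
    last <- list(pred = pred, corr = corr, P = P)
    if (rel * Tflow / solver$dt < cfg$steady_tol && nstep > 2L) {
      converged <- "steady"; break
    }
    if (state$t >= cfg$max_time - 1e-12) {
      converged <- "max_time"; break
    }
  }
  diagnostics <- as.data.frame(do.call(rbind, diag_rows))
  flow_state_from(solver, state, last, diagnostics, converged, nstep)
}

flow_state_from <- function(solver, state, last, diagnostics, converged,
                            nstep) {
  d <- solver$dims
  arrs <- vector("list", 3)
  for (m in 1:3) {
    cm <- solver$comps[[m]]
    full <- array(last$corr$full[[m]], cm$P)
    arrs[[m]] <- full[1 + seq_len(cm$Dm[1]), 1 + seq_len(cm$Dm[2]),
                      1 + seq_len(cm$Dm[3]), drop = FALSE]
  }
  Parr <- array(0, d)
  Parr[solver$cells] <- last$P
  structure(list(
    U = arrs[[1]], V = arrs[[2]], W = arrs[[3]], P = Parr,
    u_dof = state$u, t = state$t, dt = solver$dt, steps = nstep,
    converged = converged, diagnostics = diagnostics,
    dims = d, h = solver$h, spacing = solver$mask$spacing,
    mask = solver$mask
  ), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "<flow_state> %d steps to t = %.4g s (%s), max |u| = %.4g m/s\n",
    x$steps, x$t, x$converged, max(abs(x$U), abs(x$V), abs(x$W))))
  cat(sprintf("  final max divergence %.3g 1/s, flux in/out %.4g / %.4g m^3/s\n",
              utils::tail(x$diagnostics$max_div, 1),
              utils::tail(x$diagnostics$flux_in, 1),
              utils::tail(x$diagnostics$flux_out, 1)))
  invisible(x)
}

#' Cell-centred velocity vectors of a flow state
#'
#' Averages the two staggered face values per direction onto cell centres.
#'
#' @param state a `flow_state`.
#' @return list of three 3D arrays `u`, `v`, `w` (m/s) on the cell grid.
#' @export
cell_velocity <- function(state) {
  d <- state$dims
  list(
    u = 0.5 * (state$U[seq_len(d[1]), , , drop = FALSE] +
                 state$U[seq_len(d[1]) + 1L, , , drop = FALSE]),
    v = 0.5 * (state$V[, seq_len(d[2]), , drop = FALSE] +
                 state$V[, seq_len(d[2]) + 1L, , drop = FALSE]),
    w = 0.5 * (state$W[, , seq_len(d[3]), drop = FALSE] +
                 state$W[, , seq_len(d[3]) + 1L, drop = FALSE])
  )
}
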