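#' Solver configuration
#'
#' Physical and numerical parameters for the immersed-boundary flow solver.
#' Geometry is taken in mm from the imaging side and converted to SI
#' internally; all velocities are m/s and pressures Pa.
#'
#' @param rho blood density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param dt fixed time step (s); when `NULL` it is set once at start-up from
#'   the CFL target and the peak inflow speed.
#' @param cfl CFL target used to choose `dt` when `dt` is `NULL`.
#' @param poisson_tol relative tolerance bookkeeping for the pressure
#'   projection; the cached-factorization direct solve used here reaches
#'   round-off, so this acts as the acceptance bound for the post-step
#'   divergence check.
#' @param steady_tol relative L2 velocity change per flow-through time below
#'   which the run is declared steady.
#' @param max_time end of the simulated physical time window (s).
#' @param max_steps hard cap on time steps.
#' @param periodic logical length-3; periodic axes (no wall, no opening).
#'   Used by verification set-ups, not by the imaging pipeline.
#' @param verbose print per-step diagnostics.
#' @return A `solver_config` list.
#' @export
solver_config <- function(rho = 1060, mu = 0.0035, dt = NULL, cfl = 0.5,
                          poisson_tol = 1e-8, steady_tol = 1e-3,
                          max_time = 1, max_steps = 100000L,
                          periodic = c(FALSE, FALSE, FALSE), verbose = FALSE) {
  stopifnot(rho > 0, mu > 0, cfl > 0, poisson_tol > 0, steady_tol > 0,
            max_time > 0, length(periodic) == 3L)
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  structure(list(rho = rho, mu = mu, dt = dt, cfl = cfl,
                 poisson_tol = poisson_tol, steady_tol = steady_tol,
                 max_time = max_time, max_steps = as.integer(max_steps),
                 periodic = as.logical(periodic), verbose = verbose),
            class = "solver_config")
}

lin3 <- function(p, dd) p[, 1] + dd[1] * (p[, 2] - 1) + dd[1] * dd[2] * (p[, 3] - 1)

# expand.grid over padded face lattice as an n x 3 integer matrix
all_coords <- function(dd) {
  cbind(rep(seq_len(dd[1]), times = dd[2] * dd[3]),
        rep(rep(seq_len(dd[2]), each = dd[1]), times = dd[3]),
        rep(seq_len(dd[3]), each = dd[1] * dd[2]))
}

# cell lookup array with a 2-deep halo; periodic axes wrap, others are FALSE
halo_cells <- function(F, periodic) {
  d <- dim(F)
  maps <- lapply(1:3, function(ax) {
    p <- seq_len(d[ax] + 4L) - 2L
    if (periodic[ax]) ((p - 1L) %% d[ax]) + 1L
    else ifelse(p >= 1L & p <= d[ax], p, NA_integer_)
  })
  big <- array(FALSE, d + 4L)
  ok <- lapply(maps, function(m) which(!is.na(m)))
  big[ok[[1]], ok[[2]], ok[[3]]] <-
    F[maps[[1]][ok[[1]]], maps[[2]][ok[[2]]], maps[[3]][ok[[3]]]]
  big
}

# numeric halo array with nearest-edge clamping (and periodic wrap)
halo_clamp <- function(A, periodic) {
  d <- dim(A)
  maps <- lapply(1:3, function(ax) {
    p <- seq_len(d[ax] + 4L) - 2L
    if (periodic[ax]) ((p - 1L) %% d[ax]) + 1L
    else pmin(pmax(p, 1L), d[ax])
  })
  A[maps[[1]], maps[[2]], maps[[3]]]
}

#' Set up the immersed-boundary flow solver
#'
#' Classifies every staggered velocity face of the masked voxel grid (interior
#' unknown, wall-closure ghost, inflow, outflow, periodic image), derives the
#' sub-voxel wall positions from the level-set field sampled at face
#' locations, folds the ghost-fluid wall closures into the implicit
#' Crank-Nicolson operators, and assembles and factorizes the viscous and
#' pressure-Poisson matrices. The geometry is static, so all of this happens
#' once per run.
#'
#' @param mask a `lumen_mask` defining the fluid cells.
#' @param levelset a smoothed `levelset_field` on the same grid.
#' @param patches boundary patches from [identify_openings()] (may be empty
#'   for fully periodic verification set-ups).
#' @param profile an `inflow_profile` for the inflow patch, or `NULL`.
#' @param config a [solver_config()].
#' @return A `flow_solver` object (opaque; used by [run_solver()] and the
#'   stepping primitives).
#' @export
solver_setup <- function(mask, levelset, patches = list(), profile = NULL,
                         config = solver_config()) {
  stopifnot(inherits(mask, "lumen_mask"))
  if (!is.null(levelset) && !all(mask$dims == levelset$dims))
    stop("mask and level set grids differ")
  d <- mask$dims
  h <- mask$spacing * 1e-3                     # m
  per <- config$periodic
  F <- mask$mask
  Fbig <- halo_cells(F, per)
  phi <- if (is.null(levelset)) array(1, d) else levelset$phi
  phibig <- halo_clamp(phi, per)

  drop <- vapply(patches, function(p) per[p$axis], logical(1))
  if (any(drop)) {
    warning("dropping ", sum(drop), " boundary patch(es) on periodic axes")
    patches <- patches[!drop]
  }
  inflow_patch <- Filter(function(p) p$role == "inflow", patches)
  if (length(inflow_patch) > 1L)
    stop("multiple inflow patches are not supported; merge or re-segment")
  inflow_patch <- if (length(inflow_patch)) inflow_patch[[1]] else NULL
  outflow_patches <- Filter(function(p) p$role == "outflow", patches)

  # per-cell membership arrays for openings
  inflow_cells <- array(0L, d)     # row index into the inflow patch voxels
  if (!is.null(inflow_patch)) {
    v <- inflow_patch$voxels
    inflow_cells[v] <- seq_len(nrow(v))
  }
  # membership per ROI face name
  face_names <- names(face_specs(d))
  memb <- lapply(face_names, function(fn) {
    arr <- array(FALSE, d)
    for (p in patches) if (p$face == fn) arr[p$voxels] <- TRUE
    arr
  })
  names(memb) <- face_names
  memb_role <- lapply(face_names, function(fn) {
    arr <- array("", d)
    for (p in patches) if (p$face == fn) arr[p$voxels] <- p$role
    arr
  })
  names(memb_role) <- face_names

  comps <- vector("list", 3)
  for (m in 1:3) {
    comps[[m]] <- classify_component(m, d, h, per, Fbig, phibig,
                                     memb, memb_role, inflow_cells)
  }

  cells <- which(F, arr.ind = TRUE)
  n_cell <- nrow(cells)
  cell_id <- array(0L, d)
  cell_id[cells] <- seq_len(n_cell)
  cell_id_big <- halo_int(cell_id, per)

  solver <- structure(list(
    dims = d, h = h, config = config, mask = mask, levelset = levelset,
    patches = patches, profile = profile, inflow_patch = inflow_patch,
    comps = comps, cells = cells, n_cell = n_cell, cell_id = cell_id,
    cell_id_big = cell_id_big
  ), class = "flow_solver")

  solver <- build_poisson(solver, memb_role)
  solver <- build_momentum(solver)
  solver
}

halo_int <- function(A, periodic) {
  d <- dim(A)
  maps <- lapply(1:3, function(ax) {
    p <- seq_len(d[ax] + 4L) - 2L
    if (periodic[ax]) ((p - 1L) %% d[ax]) + 1L
    else ifelse(p >= 1L & p <= d[ax], p, NA_integer_)
  })
  big <- array(0L, d + 4L)
  ok <- lapply(maps, function(m) which(!is.na(m)))
  big[ok[[1]], ok[[2]], ok[[3]]] <-
    A[maps[[1]][ok[[1]]], maps[[2]][ok[[2]]], maps[[3]][ok[[3]]]]
  big
}

# Classify every padded face of component m and build the ghost chain
# (value = C %*% u_dof + g0). See the methods vignette for the face taxonomy.
classify_component <- function(m, d, h, per, Fbig, phibig, memb, memb_role,
                               inflow_cells) {
  Dm <- d; Dm[m] <- d[m] + 1L            # unpadded face counts
  P <- Dm + 2L                           # padded
  st <- c(1L, P[1], P[1] * P[2])
  npad <- prod(P)
  oth <- setdiff(1:3, m)

  # fluid cells flanking each padded face; padded face coord pf maps to
  # halo cell coords: axis m -> pf and pf+1; other axes -> pf+1
  idx <- lapply(1:3, function(ax) seq_len(P[ax]) + 1L)
  idxmL <- seq_len(P[m])
  idxmR <- idxmL + 2L
  args <- idx; args[[m]] <- idxmL
  FL <- do.call(`[`, c(list(Fbig), args))
  args[[m]] <- idxmR - 1L
  FR <- do.call(`[`, c(list(Fbig), args))

  # face-sampled level set (mean of flanking cell values, halo-clamped)
  args[[m]] <- idxmL
  phL <- do.call(`[`, c(list(phibig), args))
  args[[m]] <- idxmR - 1L
  phR <- do.call(`[`, c(list(phibig), args))
  phiface <- 0.5 * (phL + phR)

  in_range <- array(FALSE, P)
  rng <- lapply(1:3, function(ax) 1 + seq_len(Dm[ax]))
  if (per[m]) rng[[m]] <- 1 + seq_len(d[m])  # periodic: last face is an image
  in_range[rng[[1]], rng[[2]], rng[[3]]] <- TRUE

  dof <- FL & FR & in_range
  dof_id <- array(0L, P)
  n_dof <- sum(dof)
  dof_id[dof] <- seq_len(n_dof)
  pos_dof <- which(dof)
  dof_coord <- which(dof, arr.ind = TRUE)

  # ghost set: non-dof faces that either flank a fluid cell or neighbor a dof
  near_dof <- array(FALSE, P)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- shift_logical(dof, ax, s)
    near_dof <- near_dof | shifted
  }
  ghost <- (!dof) & (near_dof | FL | FR)
  ghost_id <- array(0L, P)
  n_ghost <- sum(ghost)
  ghost_id[ghost] <- seq_len(n_ghost)
  ghost_pos <- which(ghost)
  ghost_coord <- which(ghost, arr.ind = TRUE)

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  g0 <- numeric(n_ghost)
  done <- logical(n_ghost)
  # slot bookkeeping for time-dependent inflow values
  infl_norm_slot <- integer(0); infl_norm_row <- integer(0)
  infl_tan_slot <- integer(0); infl_tan_rows <- list()
  outflow_slot <- integer(0); outflow_cell <- integer(0) # filled later
  outflow_sign <- numeric(0)

  # --- periodic images -------------------------------------------------
  if (any(per)) {
    gp <- ghost_coord
    wrap <- gp
    period <- Dm; period[m] <- d[m]
    for (ax in 1:3) if (per[ax])
      wrap[, ax] <- ((gp[, ax] - 1L - 1L) %% period[ax]) + 1L + 1L
    moved <- rowSums(wrap != gp) > 0
    tgt <- dof_id[lin3(wrap, P)]
    sel <- moved & tgt > 0L & !done
    if (any(sel)) {
      trip_i <- c(trip_i, ghost_id[ghost_pos[sel]])
      trip_j <- c(trip_j, tgt[sel])
      trip_x <- c(trip_x, rep(1, sum(sel)))
      done[ghost_id[ghost_pos[sel]]] <- TRUE
    }
  }

  # --- opening faces normal to the patch axis --------------------------
  for (fn in names(memb)) {
    sp <- face_specs(d)[[fn]]
    if (sp$axis != m) next
    cells_on <- which(memb[[fn]], arr.ind = TRUE)
    if (nrow(cells_on) == 0) next
    roles <- memb_role[[fn]][cells_on]
    fc <- cells_on
    minside <- sp$index == 1L
    fc[, m] <- if (minside) 1L else d[m] + 1L
    fpad <- fc + 1L
    gi <- ghost_id[lin3(fpad, P)]
    ok <- gi > 0L & !done[pmax(gi, 1L)]
    for (w in which(ok)) {
      slot <- gi[w]
      if (roles[w] == "inflow") {
        row <- inflow_cells[matrix(cells_on[w, ], 1)]
        infl_norm_slot <- c(infl_norm_slot, slot)
        infl_norm_row <- c(infl_norm_row, row)
      } else {
        inw <- fpad[w, ]
        inw[m] <- inw[m] + if (minside) 1L else -1L
        tgt <- dof_id[lin3(matrix(inw, 1), P)]
        if (tgt > 0L) {
          trip_i <- c(trip_i, slot); trip_j <- c(trip_j, tgt)
          trip_x <- c(trip_x, 1)
        }
        outflow_slot <- c(outflow_slot, slot)
        outflow_sign <- c(outflow_sign, if (minside) -1 else 1)
      }
      done[slot] <- TRUE
    }
  }

  # --- domain-boundary tangential ghosts -------------------------------
  for (ax in oth) {
    if (per[ax]) next
    for (side in c(1L, 2L)) {
      pf_out <- if (side == 1L) 1L else P[ax]
      sel <- ghost_coord[, ax] == pf_out & !done[ghost_id[ghost_pos]]
      if (!any(sel)) next
      gsel <- ghost_coord[sel, , drop = FALSE]
      fin <- gsel
      fin[, ax] <- fin[, ax] + if (side == 1L) 1L else -1L
      tgt <- dof_id[lin3(fin, P)]
      slot <- ghost_id[lin3(gsel, P)]
      # flanking boundary cells of the inward face (cell slice at the wall)
      cslice <- if (side == 1L) 1L else d[ax]
      fname <- paste0(c("i", "j", "k")[ax], if (side == 1L) "min" else "max")
      for (w in seq_len(nrow(gsel))) {
        if (tgt[w] == 0L) { done[slot[w]] <- TRUE; next }
        cl <- face_cells_unpadded(fin[w, ], m, d)
        cl <- cl[cl[, ax] == cslice, , drop = FALSE]
        cl <- cl[valid_cells(cl, d), , drop = FALSE]
        role <- if (nrow(cl)) memb_role[[fname]][cl] else ""
        role <- role[role != ""]
        if (length(role) && role[1] == "inflow") {
          rows <- inflow_cells[cl]
          rows <- rows[rows > 0L]
          infl_tan_slot <- c(infl_tan_slot, slot[w])
          infl_tan_rows[[length(infl_tan_rows) + 1L]] <- rows
          trip_i <- c(trip_i, slot[w]); trip_j <- c(trip_j, tgt[w])
          trip_x <- c(trip_x, -1)       # u_g = 2 u_bc - u_f
        } else if (length(role) && role[1] == "outflow") {
          trip_i <- c(trip_i, slot[w]); trip_j <- c(trip_j, tgt[w])
          trip_x <- c(trip_x, 1)        # zero gradient
        } else {
          trip_i <- c(trip_i, slot[w]); trip_j <- c(trip_j, tgt[w])
          trip_x <- c(trip_x, -1)       # no-slip wall on the ROI plane
        }
        done[slot[w]] <- TRUE
      }
    }
  }

  # --- interior wall ghosts (ghost-fluid mirroring) --------------------
  remaining <- which(!done)
  if (length(remaining)) {
    rem_pos <- ghost_pos[match(remaining, ghost_id[ghost_pos])]
    cand_cnt <- numeric(length(remaining))
    cand_i <- integer(0); cand_j <- integer(0); cand_x <- numeric(0)
    slot_of <- integer(npad)
    slot_of[rem_pos] <- seq_along(remaining)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      fpos <- rem_pos + s * st[ax]
      okrange <- fpos >= 1L & fpos <= npad
      fd <- integer(length(rem_pos))
      fd[okrange] <- dof_id[fpos[okrange]]
      valid <- fd > 0L
      if (!any(valid)) next
      gsel <- rem_pos[valid]
      fsel <- fpos[valid]
      rows <- slot_of[gsel]
      cand_cnt[rows] <- cand_cnt[rows] + 1
      phf <- phiface[fsel]; phg <- phiface[gsel]
      crossing <- phf > 0 & phg < 0
      dw <- ifelse(crossing, h[ax] * phf / (phf - phg), NA_real_)
      nxt <- fsel - s * st[ax]
      okn <- nxt >= 1L & nxt <= npad
      nd <- integer(length(fsel))
      nd[okn] <- dof_id[nxt[okn]]
      has_next <- nd > 0L
      cc <- ghost_point_coefs(ifelse(is.na(dw), h[ax], dw), h[ax], has_next)
      # no crossing: treat the wall as sitting on the ghost face (value 0)
      cc[is.na(dw), ] <- 0
      use <- abs(cc[, 1]) > 0
      cand_i <- c(cand_i, rows[use])
      cand_j <- c(cand_j, dof_id[fsel[use]])
      cand_x <- c(cand_x, cc[use, 1])
      use2 <- has_next & abs(cc[, 2]) > 0
      cand_i <- c(cand_i, rows[use2])
      cand_j <- c(cand_j, nd[use2])
      cand_x <- c(cand_x, cc[use2, 2])
    }
    if (length(cand_i)) {
      wgt <- 1 / pmax(cand_cnt[cand_i], 1)
      trip_i <- c(trip_i, remaining[cand_i])
      trip_j <- c(trip_j, cand_j)
      trip_x <- c(trip_x, cand_x * wgt)
    }
  }

  C <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(max(n_ghost, 1L), max(n_dof, 1L)))
  list(m = m, Dm = Dm, P = P, st = st, h = h, n_dof = n_dof,
       n_ghost = n_ghost, dof_id = dof_id, ghost_id = ghost_id,
       pos_dof = pos_dof, ghost_pos = ghost_pos, dof_coord = dof_coord,
       C = C, g0_static = g0,
       infl_norm_slot = infl_norm_slot, infl_norm_row = infl_norm_row,
       infl_tan_slot = infl_tan_slot, infl_tan_rows = infl_tan_rows,
       outflow_slot = outflow_slot, outflow_sign = outflow_sign)
}

shift_logical <- function(A, ax, s) {
  d <- dim(A)
  out <- array(FALSE, d)
  n <- d[ax]
  src <- seq_len(n) + s
  ok <- src >= 1L & src <= n
  if (!any(ok)) return(out)
  dst <- seq_len(n)[ok]; src <- src[ok]
  if (ax == 1) out[dst, , ] <- A[src, , ]
  if (ax == 2) out[, dst, ] <- A[, src, ]
  if (ax == 3) out[, , dst] <- A[, , src]
  out
}

# the two cells flanking an (unpadded-coord) face of component m
face_cells_unpadded <- function(fpad, m, d) {
  f <- fpad - 1L
  c1 <- f; c1[m] <- f[m] - 1L
  c2 <- f
  rbind(c1, c2)
}

valid_cells <- function(cl, d) {
  cl[, 1] >= 1L & cl[, 1] <= d[1] & cl[, 2] >= 1L & cl[, 2] <= d[2] &
    cl[, 3] >= 1L & cl[, 3] <= d[3]
}
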