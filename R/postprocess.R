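#' Wall pressure at wall-adjacent fluid cells
#'
#' With a homogeneous Neumann condition on the wall-normal pressure gradient,
#' the pressure on the lumen wall equals the pressure at the adjacent fluid
#' cell centre, so the wall pressure is read off directly.
#'
#' @param state a `flow_state` from [run_solver()].
#' @param wallgeom a `wall_geometry` from [wall_distances()].
#' @return numeric vector of wall pressures (Pa), one per wall-adjacent cell.
#' @export
wall_pressure <- function(state, wallgeom) {
  stopifnot(inherits(state, "flow_state"), inherits(wallgeom, "wall_geometry"))
  state$P[wallgeom$cells]
}

#' Velocity-gradient tensor at wall-adjacent cells
#'
#' Computes the full velocity-gradient tensor at each wall-adjacent fluid
#' cell from cell-centred velocities and boundary velocities at the cell
#' faces. Per direction: if exactly one neighbor cell is outside the mask,
#' a one-sided difference between the cell value and the wall-face boundary
#' velocity over half a spacing (sign-consistent: fluid-side minus wall-side
#' over the distance); if both neighbors are outside, the difference of the
#' two face boundary values over one spacing; otherwise a standard central
#' difference. For the component normal to the face the staggered face value
#' is the boundary velocity; for tangential components the boundary value is
#' reconstructed with the ghost-fluid face closure [ghost_face_velocity()]
#' from the cell-centred samples and the level-set wall distances.
#'
#' @param state a `flow_state`.
#' @param wallgeom a `wall_geometry` (provides the cells and distances).
#' @return array `n x 3 x 3`; entry `[c, i, j]` is `du_i/dx_j` (1/s) at wall
#'   cell `c`.
#' @export
near_wall_gradient <- function(state, wallgeom) {
  stopifnot(inherits(state, "flow_state"), inherits(wallgeom, "wall_geometry"))
  M <- state$mask$mask
  d <- state$dims
  h <- state$h
  uc <- cell_velocity(state)
  ucl <- list(uc$u, uc$v, uc$w)
  faces <- list(state$U, state$V, state$W)
  cells <- wallgeom$cells
  n <- nrow(cells)
  grad <- array(0, c(n, 3, 3))
  Mf <- function(cc) {
    ok <- valid_cells(cc, d)
    out <- logical(nrow(cc))
    out[ok] <- M[cc[ok, , drop = FALSE]]
    out
  }
  inside <- function(cc) valid_cells(cc, d)
  for (ax in 1:3) {
    cp <- cells; cp[, ax] <- cp[, ax] + 1L
    cmn <- cells; cmn[, ax] <- cmn[, ax] - 1L
    fp <- Mf(cp)   # + neighbor is fluid
    fm <- Mf(cmn)
    ep <- !inside(cp)   # + neighbor beyond the ROI (an opening, not a wall)
    em <- !inside(cmn)
    # distance from the cell centre to the wall on each side (m)
    dsgn <- -wallgeom$d[, ax] * 1e-3      # + : wall on the + side
    dist_p <- ifelse(!fp, ifelse(is.na(dsgn) | dsgn <= 0, h[ax] / 2,
                                 pmin(dsgn, h[ax])), NA)
    dist_m <- ifelse(!fm, ifelse(is.na(dsgn) | dsgn >= 0, h[ax] / 2,
                                 pmin(-dsgn, h[ax])), NA)
    for (comp in 1:3) {
      u0 <- ucl[[comp]][cells]
      up <- numeric(n); um <- numeric(n)
      up[fp] <- ucl[[comp]][cp[fp, , drop = FALSE]]
      um[fm] <- ucl[[comp]][cmn[fm, , drop = FALSE]]
      # boundary values on cut faces
      if (any(!fp)) up[!fp] <- face_bc_value(comp, ax, +1L, cells, !fp,
                                             faces, ucl, dist_p, h, Mf)
      if (any(!fm)) um[!fm] <- face_bc_value(comp, ax, -1L, cells, !fm,
                                             faces, ucl, dist_m, h, Mf)
      g <- numeric(n)
      both <- fp & fm
      g[both] <- (up[both] - um[both]) / (2 * h[ax])
      onlyp <- !fp & fm & !ep
      g[onlyp] <- (up[onlyp] - u0[onlyp]) / (h[ax] / 2)
      onlym <- fp & !fm & !em
      g[onlym] <- (u0[onlym] - um[onlym]) / (h[ax] / 2)
      none <- !fp & !fm & !ep & !em
      g[none] <- (up[none] - um[none]) / h[ax]
      # ROI-edge neighbors are openings, not walls: one-sided fluid
      # difference over one spacing toward the interior
      edgep <- ep & fm
      g[edgep] <- (u0[edgep] - um[edgep]) / h[ax]
      edgem <- em & fp
      g[edgem] <- (up[edgem] - u0[edgem]) / h[ax]
      ew <- ep & !fm & !em           # edge on +, wall on -
      g[ew] <- (u0[ew] - um[ew]) / (h[ax] / 2)
      we <- em & !fp & !ep           # wall on +, edge on -
      g[we] <- (up[we] - u0[we]) / (h[ax] / 2)
      grad[, comp, ax] <- g
    }
  }
  grad
}

# boundary velocity of `comp` on the face of `cells` in direction (ax, s),
# for the rows selected by `sel`
face_bc_value <- function(comp, ax, s, cells, sel, faces, ucl, dist, h, Mf) {
  idx <- which(sel)
  cc <- cells[idx, , drop = FALSE]
  if (comp == ax) {
    # staggered face value is stored in the state
    fc <- cc
    if (s > 0) fc[, ax] <- fc[, ax] + 1L
    faces[[comp]][fc]
  } else {
    u_near <- ucl[[comp]][cc]
    nxt <- cc; nxt[, ax] <- nxt[, ax] - s
    okn <- Mf(nxt)
    u_next <- rep(NA_real_, length(idx))
    u_next[okn] <- ucl[[comp]][nxt[okn, , drop = FALSE]]
    d <- dist[idx]
    # two-point ghost extrapolation for all d where a second sample exists:
    # linear-exact like the interpolation branch but with bounded
    # coefficients, so sliver cells (wall almost on the cell centre) do not
    # amplify discretization noise into the gradient
    two <- !is.na(u_next)
    out <- numeric(length(idx))
    out[two] <- (u_near[two] - u_next[two]) * (h[ax] / 2 - d[two]) / h[ax]
    out[!two] <- ghost_face_velocity(u_near[!two], NA_real_, d[!two], h[ax])
    out
  }
}

#' Wall shear stress from near-wall velocity gradients
#'
#' The viscous traction tangential to the wall,
#' \deqn{\tau_w = \mu ( \nabla u \cdot n - ((\nabla u \cdot n)\cdot n)\, n ),}
#' with `n` the unit level-set normal. The WSS vector is tangential to the
#' wall by construction and is stored on the wall-adjacent fluid cell.
#'
#' @param grad `n x 3 x 3` gradient array from [near_wall_gradient()].
#' @param wallgeom a `wall_geometry` (provides unit normals).
#' @param mu dynamic viscosity (Pa s).
#' @return A `wall_field`: list with `cells`, `tau` (n x 3, Pa), `tau_mag`,
#'   `normals`.
#' @export
wall_shear_stress <- function(grad, wallgeom, mu) {
  nrm <- wallgeom$normals
  n <- nrow(nrm)
  Gn <- matrix(0, n, 3)
  for (i in 1:3)
    Gn[, i] <- grad[, i, 1] * nrm[, 1] + grad[, i, 2] * nrm[, 2] +
      grad[, i, 3] * nrm[, 3]
  Gnn <- rowSums(Gn * nrm)
  tau <- mu * (Gn - Gnn * nrm)
  tau[is.na(tau)] <- 0
  structure(
    list(cells = wallgeom$cells, tau = tau,
         tau_mag = sqrt(rowSums(tau^2)), normals = nrm),
    class = "wall_field"
  )
}

#' @export
print.wall_field <- function(x, ...) {
  cat(sprintf("<wall_field> %d wall cells, |tau| in [%.4g, %.4g] Pa\n",
              nrow(x$cells), min(x$tau_mag), max(x$tau_mag)))
  invisible(x)
}

#' Label the aneurysm region of a mask from a phantom truth
#'
#' @param mask a `lumen_mask`.
#' @param truth a `phantom_truth` with an `aneurysm` predicate (see
#'   [sidewall_aneurysm_phantom()]).
#' @return logical array over the grid, `TRUE` on lumen cells inside the
#'   aneurysm region.
#' @export
aneurysm_region_from_truth <- function(mask, truth) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(truth, "phantom_truth"))
  if (is.null(truth$aneurysm)) stop("truth has no aneurysm predicate")
  pts <- grid_points(mask$dims, mask$spacing)
  pts <- sweep(pts, 2, mask$origin, `+`)
  array(truth$aneurysm(pts), mask$dims) & mask$mask
}

#' Normalized hemodynamic metrics over an aneurysm region
#'
#' The WSS magnitude on aneurysm-wall cells is normalized by the inflow
#' dynamic pressure, `tau* = |tau_w| / (rho U0^2)`, and summarized by its
#' maximum, mean and variation (population standard deviation). The flow
#' strength inside the aneurysm is the volume-averaged normalized speed
#' `(|u|/U0)_avg` over the region's cells.
#'
#' @param wallfield a `wall_field` from [wall_shear_stress()].
#' @param state a `flow_state`.
#' @param region logical array over the grid labelling the aneurysm cells
#'   (see [aneurysm_region_from_truth()]), or an n x 3 index matrix.
#' @param U0 inflow normalization velocity (m/s).
#' @param rho blood density (kg/m^3).
#' @return A `hemodynamic_metrics` list: `tau_star_max`, `tau_star_avg`,
#'   `tau_star_var`, `vel_ratio_avg`, `n_wall_cells`, `n_region_cells`.
#' @export
aneurysm_metrics <- function(wallfield, state, region, U0, rho = 1060) {
  stopifnot(inherits(wallfield, "wall_field"), U0 > 0, rho > 0)
  d <- state$dims
  reg <- if (is.matrix(region)) {
    arr <- array(FALSE, d); arr[region] <- TRUE; arr
  } else region
  if (!any(reg)) stop("empty aneurysm region")
  on_wall <- reg[wallfield$cells]
  if (!any(on_wall)) stop("aneurysm region has no wall-adjacent cells")
  tstar <- wallfield$tau_mag[on_wall] / (rho * U0^2)
  uc <- cell_velocity(state)
  speed <- sqrt(uc$u^2 + uc$v^2 + uc$w^2)
  vavg <- mean(speed[reg]) / U0
  structure(list(
    tau_star_max = max(tstar),
    tau_star_avg = mean(tstar),
    tau_star_var = stats::sd(tstar) * sqrt((length(tstar) - 1) /
                                             length(tstar)),
    vel_ratio_avg = vavg,
    n_wall_cells = sum(on_wall),
    n_region_cells = sum(reg)
  ), class = "hemodynamic_metrics")
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<hemodynamic_metrics> tau*_max = %.4g, tau*_avg = %.4g, ",
    "tau*_var = %.4g, (|u|/U0)_avg = %.4g\n"),
    x$tau_star_max, x$tau_star_avg, x$tau_star_var, x$vel_ratio_avg))
  invisible(x)
}

#' Aneurysm size ratio
#'
#' `SR = (aneurysm maximal length) / (parent vessel diameter)`: the maximal
#' length is the largest pairwise distance between aneurysm-region cell
#' centres; the parent diameter defaults to twice the rim radius `R'_max` of
#' the inflow centerline frame when not supplied.
#'
#' @param region logical array or n x 3 index matrix of aneurysm cells.
#' @param mask the `lumen_mask` (for grid geometry).
#' @param frame optional `centerline_frame` with `Rprime_max` (mm).
#' @param parent_diameter optional parent vessel diameter (mm), overriding
#'   the frame estimate.
#' @return SR (dimensionless).
#' @export
size_ratio <- function(region, mask, frame = NULL, parent_diameter = NULL) {
  if (is.null(parent_diameter)) {
    if (is.null(frame) || is.null(frame$Rprime_max))
      stop("need a centerline frame with rim radius or an explicit diameter")
    parent_diameter <- 2 * frame$Rprime_max
  }
  if (parent_diameter <= 0) stop("degenerate parent diameter")
  cells <- if (is.matrix(region)) region else which(region, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty aneurysm region")
  pts <- sweep(sweep(cells - 0.5, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  max_extent(pts) / parent_diameter
}

# largest pairwise distance of a point cloud; exact for moderate n, shell
# pre-selection by directional extremes for large n
max_extent <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  if (n > 4000L) {
    gold <- pi * (3 - sqrt(5))
    k <- seq_len(200L)
    dirs <- cbind(cos(gold * k) * sqrt(1 - ((2 * k - 1) / 200 - 1)^2),
                  sin(gold * k) * sqrt(1 - ((2 * k - 1) / 200 - 1)^2),
                  (2 * k - 1) / 200 - 1)
    proj <- pts %*% t(dirs)
    keep <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    pts <- pts[keep, , drop = FALSE]
  }
  max(stats::dist(pts))
}
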