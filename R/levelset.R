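#' Build the level-set field from image intensity
#'
#' The raw level set is the thresholded intensity, `phi0 = I - I0`, so the
#' lumen wall is the `phi = 0` iso-surface, with `phi > 0` inside the lumen.
#' The returned field starts with `phi = phi0`; apply [smooth_levelset()] to
#' low-pass filter it before geometric queries (done by default in the
#' pipeline).
#'
#' @param vol an [intensity_volume()].
#' @param I0 threshold intensity (scanner units).
#' @return A `levelset_field`: list with `phi0`, `phi` (3D arrays, scanner
#'   units), `I0`, `spacing`, `origin`, `dims`, `smoothed` flag.
#' @export
build_levelset <- function(vol, I0) {
  stopifnot(inherits(vol, "intensity_volume"))
  phi0 <- vol$data - I0
  structure(
    list(phi0 = phi0, phi = phi0, I0 = I0, spacing = vol$spacing,
         origin = vol$origin, dims = vol$dims, smoothed = FALSE),
    class = "levelset_field"
  )
}

#' @export
print.levelset_field <- function(x, ...) {
  cat(sprintf("<levelset_field> %d x %d x %d, phi in [%.4g, %.4g]%s\n",
              x$dims[1], x$dims[2], x$dims[3], min(x$phi), max(x$phi),
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

# one-dimensional (1/4, 1/2, 1/4) filter along `axis` with edge replication
filter3_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  lo <- c(1, seq_len(n - 1))   # shifted index: nearest-edge replication
  hi <- c(seq_len(n - 1) + 1, n)
  take <- function(idx) {
    switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
  }
  0.25 * take(lo) + 0.5 * arr + 0.25 * take(hi)
}

#' Smooth the level-set field with the 27-point low-pass filter
#'
#' Applies the separable 3x3x3 filter with weights
#' `(1/2)^3 * (1/2)^(|p|+|q|+|r|)` (centre weight 1/8, face neighbors 1/16,
#' edge 1/32, corner 1/64; weights sum to exactly 1, so a constant field is a
#' fixed point). At the volume boundary, out-of-range neighbors are replaced
#' by the nearest edge value, which keeps the weight sum at 1 there too. The
#' filter is linear and positivity-preserving; repeated application diffuses
#' toward a constant.
#'
#' @param ls a `levelset_field` from [build_levelset()].
#' @return The field with `phi` replaced by the filtered `phi`.
#' @export
smooth_levelset <- function(ls) {
  stopifnot(inherits(ls, "levelset_field"))
  phi <- ls$phi
  for (ax in 1:3) phi <- filter3_axis(phi, ax)
  ls$phi <- phi
  ls$smoothed <- TRUE
  ls
}

# central-difference gradient along one axis with one-sided differences at the
# array boundary; h is the spacing along that axis (result per mm)
grad_axis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  lo <- c(1, seq_len(n - 1))
  hi <- c(seq_len(n - 1) + 1, n)
  denom <- array(2 * h, d)
  edge <- function(idx_one, val) {
    switch(axis,
           denom[idx_one, , ] <<- val,
           denom[, idx_one, ] <<- val,
           denom[, , idx_one] <<- val)
  }
  edge(1, h); edge(n, h)
  take <- function(idx) {
    switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
  }
  (take(hi) - take(lo)) / denom
}

#' Per-direction sub-voxel wall distances at wall-adjacent fluid cells
#'
#' At each masked fluid cell with at least one face-neighbor outside the mask,
#' the signed distance to the `phi = 0` wall along each axis is estimated from
#' the level set as `d = phi / (dphi/dx)` (and likewise for y, z), with
#' central-difference gradients. The linear zero crossing along `+x` sits at
#' offset `-d_x` from the cell centre, so for a fluid cell (`phi > 0`) a wall
#' on the `+x` side gives `d_x < 0`. A direction is marked `NA` when its
#' gradient is degenerate (`|dphi| < 1e-8 * max|phi| / h`) or when the implied
#' wall is farther than `1.5` spacings (a wall that far is not this cell's
#' wall in that direction).
#'
#' @param ls a (smoothed) `levelset_field`.
#' @param mask a `lumen_mask` on the same grid.
#' @return A `wall_geometry`: list with `cells` (n x 3 indices of
#'   wall-adjacent fluid cells), `d` (n x 3 signed distances, mm, `NA` where
#'   undefined), `normals` (n x 3 unit vectors, pointing into the lumen) and
#'   `spacing`.
#' @export
wall_distances <- function(ls, mask) {
  stopifnot(inherits(ls, "levelset_field"), inherits(mask, "lumen_mask"))
  if (!all(ls$dims == mask$dims)) stop("level set and mask grids differ")
  M <- mask$mask
  adj <- wall_adjacent(M)
  cells <- which(adj & M, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("mask has no wall-adjacent cells")
  g <- lapply(1:3, function(ax) grad_axis(ls$phi, ax, ls$spacing[ax]))
  nrm <- normals_at(g, cells)
  phi_c <- ls$phi[cells]
  d <- matrix(NA_real_, nrow(cells), 3)
  for (ax in 1:3) {
    gax <- g[[ax]][cells]
    eps <- 1e-8 * max(abs(ls$phi)) / ls$spacing[ax]
    dd <- phi_c / gax
    dd[abs(gax) < eps] <- NA
    dd[abs(dd) > 1.5 * ls$spacing[ax]] <- NA
    d[, ax] <- dd
  }
  degenerate <- rowSums(!is.na(d)) == 0 & rowSums(is.na(nrm)) > 0
  if (any(degenerate))
    message(sum(degenerate), " wall cells have no usable direction; ",
            "falling back to d = spacing/2")
  structure(
    list(cells = cells, d = d, normals = nrm, spacing = ls$spacing,
         dims = ls$dims),
    class = "wall_geometry"
  )
}

# logical array: cell has at least one 6-neighbor outside the mask (domain
# edge does not count as wall)
wall_adjacent <- function(M) {
  d <- dim(M)
  out <- array(FALSE, d)
  shift_or <- function(ax, s) {
    idx <- seq_len(d[ax]) + s
    valid <- idx >= 1 & idx <= d[ax]
    src <- idx[valid]
    dst <- seq_len(d[ax])[valid]
    nb <- array(FALSE, d)
    if (ax == 1) nb[dst, , ] <- !M[src, , ]
    if (ax == 2) nb[, dst, ] <- !M[, src, ]
    if (ax == 3) nb[, , dst] <- !M[, , src]
    nb
  }
  for (ax in 1:3) for (s in c(-1L, 1L)) out <- out | shift_or(ax, s)
  out & M
}

normals_at <- function(g, cells) {
  nr <- cbind(g[[1]][cells], g[[2]][cells], g[[3]][cells])
  nn <- sqrt(rowSums(nr^2))
  bad <- nn == 0
  nr <- nr / ifelse(nn == 0, 1, nn)
  nr[bad, ] <- NA
  nr
}

#' Unit wall normals from the level set
#'
#' Normals are the normalized level-set gradient, `n = grad(phi)/|grad(phi)|`,
#' evaluated by central differences (one-sided at the volume edge). They point
#' into the lumen (direction of increasing `phi`). Cells with zero gradient
#' get `NA` normals.
#'
#' @param ls a `levelset_field`.
#' @param cells optional n x 3 matrix of voxel indices; default all voxels.
#' @return n x 3 matrix of unit normals (or a 4D array `dims x 3` when
#'   `cells` is `NULL`).
#' @export
wall_normals <- function(ls, cells = NULL) {
  stopifnot(inherits(ls, "levelset_field"))
  g <- lapply(1:3, function(ax) grad_axis(ls$phi, ax, ls$spacing[ax]))
  if (is.null(cells)) {
    nn <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
    nz <- ifelse(nn == 0, NA, nn)
    out <- array(NA_real_, c(ls$dims, 3))
    for (ax in 1:3) out[, , , ax] <- g[[ax]] / nz
    out
  } else {
    normals_at(g, cells)
  }
}
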