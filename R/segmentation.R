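#' Seeded 3D region growing segmentation
#'
#' Flood-fills the lumen from a seed voxel over face-connected (6-neighbor)
#' voxels. A neighbor is accepted iff its intensity exceeds the threshold
#' (`I > I0`) and, when `grad_max` is given, the intensity jump from the
#' accepting voxel is below it (`|I_neighbor - I_current| < grad_max`).
#' Growth stops when no further voxel can be added; bright voxels not
#' face-connected to the seed stay unmasked, which is what automatically
#' cleans up vessels disconnected from the target.
#'
#' @param vol an [intensity_volume()] (typically an ROI from [extract_roi()]).
#' @param seed integer length-3 voxel index (1-based) inside the lumen;
#'   must satisfy `I(seed) > I0`.
#' @param I0 threshold intensity (scanner units).
#' @param grad_max optional maximum intensity jump between the accepting voxel
#'   and the candidate; `NULL` disables the gradient criterion.
#' @return A `lumen_mask`: list with `mask` (logical 3D array), `seed`, `I0`,
#'   `grad_max`, `spacing`, `origin`, `dims`.
#' @examples
#' ph <- straight_tube_phantom(c(16, 16, 12), rep(0.3, 3), radius = 1)
#' m <- region_grow(ph$volume, seed = c(8, 8, 6), I0 = 500)
#' sum(m$mask)
#' @export
region_grow <- function(vol, seed, I0, grad_max = NULL) {
  stopifnot(inherits(vol, "intensity_volume"))
  seed <- as.integer(seed)
  d <- vol$dims
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel out of bounds")
  I <- vol$data
  sidx <- seed[1] + d[1] * (seed[2] - 1L) + d[1] * d[2] * (seed[3] - 1L)
  if (I[sidx] <= I0)
    stop("seed intensity (", signif(I[sidx], 6), ") does not exceed I0 (",
         signif(I0, 6), "): wrong seed or wrong threshold")
  n <- prod(d)
  state <- raw(n)                      # 0 unvisited, 1 in mask
  state[sidx] <- as.raw(1)
  frontier <- sidx
  # precomputed neighbor offsets in linear index space; boundary crossings
  # are filtered with explicit per-axis index checks below
  strides <- c(1L, d[1], d[1] * d[2])
  while (length(frontier)) {
    # coordinates of the frontier, recovered from linear indices
    f0 <- frontier - 1L
    fi <- f0 %% d[1]
    fj <- (f0 %/% d[1]) %% d[2]
    fk <- f0 %/% (d[1] * d[2])
    cand_from <- integer(0)
    cand <- integer(0)
    for (ax in 1:3) {
      co <- list(fi, fj, fk)[[ax]]
      for (s in c(-1L, 1L)) {
        ok <- if (s < 0) co > 0L else co < d[ax] - 1L
        if (!any(ok)) next
        cand <- c(cand, frontier[ok] + s * strides[ax])
        cand_from <- c(cand_from, frontier[ok])
      }
    }
    keep <- state[cand] == as.raw(0) & I[cand] > I0
    if (!is.null(grad_max))
      keep <- keep & abs(I[cand] - I[cand_from]) < grad_max
    cand <- cand[keep]
    if (!length(cand)) break
    cand <- unique(cand)
    state[cand] <- as.raw(1)
    frontier <- cand
  }
  mask <- array(state == as.raw(1), d)
  structure(
    list(mask = mask, seed = seed, I0 = I0, grad_max = grad_max,
         spacing = vol$spacing, origin = vol$origin, dims = d),
    class = "lumen_mask"
  )
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("<lumen_mask> %d of %d voxels masked (seed %s, I0 = %.4g)\n",
              sum(x$mask), prod(x$dims),
              paste(x$seed, collapse = ","), x$I0))
  invisible(x)
}

face_specs <- function(dims) {
  list(
    imin = list(axis = 1L, index = 1L),
    imax = list(axis = 1L, index = dims[1]),
    jmin = list(axis = 2L, index = 1L),
    jmax = list(axis = 2L, index = dims[2]),
    kmin = list(axis = 3L, index = 1L),
    kmax = list(axis = 3L, index = dims[3])
  )
}

# 4-connected components of a logical 2D slice; returns integer label matrix
label_components_2d <- function(sl) {
  d <- dim(sl)
  lab <- matrix(0L, d[1], d[2])
  nextlab <- 0L
  idx_all <- which(sl)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- start
    lab[start] <- nextlab
    while (length(frontier)) {
      f0 <- frontier - 1L
      r <- f0 %% d[1]
      cand <- c(frontier[r > 0L] - 1L, frontier[r < d[1] - 1L] + 1L,
                frontier[f0 %/% d[1] > 0L] - d[1],
                frontier[f0 %/% d[1] < d[2] - 1L] + d[1])
      cand <- unique(cand[sl[cand] & lab[cand] == 0L])
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab
}

#' Identify flow-domain openings on the ROI faces
#'
#' Masked voxels lying on the six faces of the ROI box are where vessels cross
#' the domain boundary. On each face, face-connected (within-slice
#' 4-connected) components of masked voxels become boundary patches. The patch
#' on the user-named inflow face takes the inflow role (the largest one, with
#' a warning, if that face carries several); every other patch is an outflow.
#'
#' @param mask a `lumen_mask` from [region_grow()].
#' @param inflow_face one of `"imin"`, `"imax"`, `"jmin"`, `"jmax"`, `"kmin"`,
#'   `"kmax"`.
#' @return A list of `boundary_patch` objects: `face`, `axis`, `slice_index`,
#'   `voxels` (n x 3 integer matrix), `centroid_mm`, `role`.
#' @export
identify_openings <- function(mask, inflow_face) {
  stopifnot(inherits(mask, "lumen_mask"))
  specs <- face_specs(mask$dims)
  if (!inflow_face %in% names(specs))
    stop("inflow_face must be one of ", paste(names(specs), collapse = ", "))
  patches <- list()
  for (fname in names(specs)) {
    sp <- specs[[fname]]
    sl <- slice_mask(mask$mask, sp$axis, sp$index)
    if (!any(sl)) next
    lab <- label_components_2d(sl)
    for (l in seq_len(max(lab))) {
      vox2 <- which(lab == l, arr.ind = TRUE)
      vox <- slice_to_vol_idx(vox2, sp$axis, sp$index)
      centroid <- colMeans(sweep(vox - 0.5, 2, mask$spacing, `*`)) + mask$origin
      patches[[length(patches) + 1L]] <- structure(
        list(face = fname, axis = sp$axis, slice_index = sp$index,
             voxels = vox, centroid_mm = centroid, role = "outflow"),
        class = "boundary_patch"
      )
    }
  }
  on_inflow <- vapply(patches, function(p) p$face == inflow_face, logical(1))
  if (!any(on_inflow))
    stop("no masked voxels on the named inflow face ", inflow_face)
  cand <- which(on_inflow)
  if (length(cand) > 1L) {
    sizes <- vapply(patches[cand], function(p) nrow(p$voxels), numeric(1))
    warning("multiple patches on the inflow face; taking the largest")
    cand <- cand[which.max(sizes)]
  }
  patches[[cand]]$role <- "inflow"
  patches
}

slice_mask <- function(arr, axis, index) {
  switch(axis, arr[index, , ], arr[, index, ], arr[, , index])
}

slice_to_vol_idx <- function(vox2, axis, index) {
  n <- nrow(vox2)
  out <- matrix(0L, n, 3)
  others <- setdiff(1:3, axis)
  out[, axis] <- index
  out[, others[1]] <- vox2[, 1]
  out[, others[2]] <- vox2[, 2]
  out
}

#' @export
print.boundary_patch <- function(x, ...) {
  cat(sprintf("<boundary_patch> %s on face %s, %d voxels, centroid (%s) mm\n",
              x$role, x$face, nrow(x$voxels),
              paste(signif(x$centroid_mm, 4), collapse = ", ")))
  invisible(x)
}
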