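#' Local vessel centerline frame at a boundary patch
#'
#' Computes mask-weighted centroids of the first `depth` slices inward from
#' the patch's ROI face,
#' \deqn{x_c(k) = \sum M x / \sum M,}
#' and the local unit centerline tangent as the least-squares line direction
#' through those centroids, oriented to point into the domain. With
#' `depth = 2` this reduces to the normalized two-point centroid difference.
#' The slice sums run over the full ROI cross-section, which assumes the mask
#' has already been cleaned to the single lumen of interest (as
#' [region_grow()] guarantees).
#'
#' @param mask a `lumen_mask`.
#' @param patch a `boundary_patch` from [identify_openings()].
#' @param depth number of slices used for the tangent fit (default 4).
#' @return A `centerline_frame`: `centers` (depth x 3, mm), `tangent` (unit,
#'   into the domain), `axis`, `face`, `patch`.
#' @export
vessel_centerline <- function(mask, patch, depth = 4L) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(patch, "boundary_patch"))
  d <- mask$dims
  ax <- patch$axis
  inward <- if (patch$slice_index == 1L) 1L else -1L
  idx <- patch$slice_index + (seq_len(depth) - 1L) * inward
  if (any(idx < 1L | idx > d[ax]))
    stop("depth exceeds the ROI extent along the face-normal axis")
  centers <- matrix(NA_real_, depth, 3)
  for (s in seq_len(depth)) {
    sl <- slice_mask(mask$mask, ax, idx[s])
    if (!any(sl)) stop("empty mask slice at index ", idx[s],
                       ": the vessel leaves the ROI laterally")
    vox2 <- which(sl, arr.ind = TRUE)
    vox <- slice_to_vol_idx(vox2, ax, idx[s])
    centers[s, ] <- colMeans(sweep(vox - 0.5, 2, mask$spacing, `*`)) +
      mask$origin
  }
  if (depth == 2L) {
    tangent <- normalize(centers[2, ] - centers[1, ])
  } else {
    cc <- sweep(centers, 2, colMeans(centers))
    sv <- svd(cc, nu = 0, nv = 1)
    tangent <- normalize(sv$v[, 1])
  }
  # orient into the domain
  if (sum(tangent * (centers[depth, ] - centers[1, ])) < 0) tangent <- -tangent
  structure(
    list(centers = centers, tangent = tangent, axis = ax, face = patch$face,
         patch = patch, spacing = mask$spacing, origin = mask$origin),
    class = "centerline_frame"
  )
}

#' @export
print.centerline_frame <- function(x, ...) {
  cat(sprintf("<centerline_frame> face %s, tangent (%s)\n", x$face,
              paste(signif(x$tangent, 4), collapse = ", ")))
  if (!is.null(x$Rprime_max))
    cat(sprintf("  rim radius R'_max = %.4g mm over %d patch voxels\n",
                x$Rprime_max, nrow(x$Rprime)))
  invisible(x)
}

#' In-plane radius vectors on the inflow patch
#'
#' For each patch voxel, the radius vector from the boundary-slice centre
#' point, `R = x - x_c`, is projected off the centerline tangent by vector
#' rejection,
#' \deqn{R' = R - (R \cdot s) s,}
#' giving the in-plane radius used by the radial inflow profiles. The rim
#' radius `R'_max` is the maximum `|R'|` over the patch.
#'
#' @param frame a `centerline_frame` from [vessel_centerline()].
#' @return The frame with `Rprime` (n x 3, mm), `Rprime_norm` (n), and
#'   `Rprime_max` (mm) added; rows align with `frame$patch$voxels`.
#' @export
inplane_radius <- function(frame) {
  stopifnot(inherits(frame, "centerline_frame"))
  vox <- frame$patch$voxels
  x <- sweep(sweep(vox - 0.5, 2, frame$spacing, `*`), 2, frame$origin, `+`)
  R <- sweep(x, 2, frame$centers[1, ])
  s <- frame$tangent
  Rp <- R - (R %*% s) %*% t(s)
  frame$Rprime <- Rp
  frame$Rprime_norm <- sqrt(rowSums(Rp^2))
  frame$Rprime_max <- max(frame$Rprime_norm)
  frame
}
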