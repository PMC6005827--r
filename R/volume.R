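#' Intensity volume container
#'
#' A 3D scalar contrast field on a regular voxel lattice, the raw input of the
#' pipeline and the geometry source for the simulation grid. Voxel indices are
#' 1-based; voxel `(i, j, k)` spans `[(i-1)*dx, i*dx)` along x (measured from
#' `origin`), so its centre sits at `origin + (i - 1/2) * spacing`.
#'
#' @param data numeric 3D array of intensities (scanner units, arbitrary scale).
#' @param spacing numeric length-3, voxel size in mm per axis; all `> 0`.
#' @param origin numeric length-3, position (mm) of the corner of voxel
#'   `(1,1,1)`. Default `c(0, 0, 0)`.
#' @return An object of class `intensity_volume` with fields `data`, `spacing`,
#'   `origin`, `dims`.
#' @examples
#' v <- intensity_volume(array(0, c(4, 4, 4)), spacing = c(0.25, 0.25, 0.25))
#' dim(v$data)
#' @export
intensity_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three finite positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(dim(data) < 2L))
    stop("all volume dimensions must be >= 2")
  if (any(!is.finite(data)))
    stop("intensities must all be finite")
  structure(
    list(data = data, spacing = spacing, origin = origin, dims = dim(data)),
    class = "intensity_volume"
  )
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf(
    "<intensity_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#'
#' @param vol an `intensity_volume` (or any list with `dims`, `spacing`,
#'   `origin`).
#' @param axis integer 1, 2 or 3.
#' @return numeric vector of cell-centre positions in mm.
#' @keywords internal
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(vol$dims[axis]) - 0.5) * vol$spacing[axis]
}

#' Read a NIfTI-1 intensity volume
#'
#' Reads a single-channel 3D NIfTI-1 file into an [intensity_volume()]. Only
#' axis-aligned volumes are supported: the voxel lattice is used directly as
#' the Cartesian simulation grid, so oblique affines are rejected rather than
#' resampled.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [intensity_volume()]; spacing is taken from the header (mm),
#'   intensities are preserved bit-exactly for integer on-disk types.
#' @export
read_intensity_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3D single-channel volume, got ", length(d), " dimensions")
  }
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  spacing <- as.numeric(pix[1:3])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("header voxel spacing must be positive in every axis")
  aff <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(aff, "try-error") && is.matrix(aff) && all(dim(aff)[1:2] == c(4, 4))) {
    rot <- aff[1:3, 1:3]
    off <- rot
    diag(off) <- 0
    if (max(abs(off)) > 1e-4 * max(abs(diag(rot)), spacing))
      stop("unsupported orientation: affine is not axis-aligned (diagonal up to sign)")
    # header translation taken as the lattice origin; axis flips in the
    # affine are ignored (the stored voxel order is used as the grid)
    origin <- as.numeric(aff[1:3, 4])
  }
  intensity_volume(array(as.numeric(img), d), spacing = spacing, origin = origin)
}

#' Write an intensity volume as NIfTI-1
#'
#' Round-trip companion of [read_intensity_volume()]. Integer-valued data is
#' written as 32-bit integers (lossless); anything else as 64-bit float.
#'
#' @param vol an [intensity_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_intensity_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  x <- vol$data
  is_int <- all(x == round(x)) && max(abs(x)) < 2^31 - 1
  attr(x, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(x, datatype = if (is_int) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rectangular region of interest in voxel indices
#'
#' Inclusive, 1-based index ranges selecting the Cartesian sub-box around a
#' target structure (e.g. an aneurysm plus sufficient upstream/downstream
#' vessel).
#'
#' @param i,j,k integer length-2 vectors `c(min, max)` per axis.
#' @return An object of class `roi_box`.
#' @examples
#' roi_box(c(5, 20), c(5, 20), c(1, 32))
#' @export
roi_box <- function(i, j, k) {
  rng <- list(i = as.integer(i), j = as.integer(j), k = as.integer(k))
  for (ax in names(rng)) {
    r <- rng[[ax]]
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 1L)
      stop("roi range for axis ", ax, " must be c(min, max) with 1 <= min <= max")
  }
  structure(rng, class = "roi_box")
}

#' Extract a region of interest
#'
#' Crops an intensity volume to an inclusive index box. Spacing is preserved
#' and the origin shifted so physical coordinates of retained voxels are
#' unchanged.
#'
#' @param vol an [intensity_volume()].
#' @param roi a [roi_box()].
#' @return The cropped [intensity_volume()].
#' @export
extract_roi <- function(vol, roi) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(roi, "roi_box"))
  d <- vol$dims
  if (roi$i[2] > d[1] || roi$j[2] > d[2] || roi$k[2] > d[3])
    stop("roi exceeds volume extent")
  sub <- vol$data[roi$i[1]:roi$i[2], roi$j[1]:roi$j[2], roi$k[1]:roi$k[2],
                  drop = FALSE]
  shift <- (c(roi$i[1], roi$j[1], roi$k[1]) - 1L) * vol$spacing
  intensity_volume(sub, spacing = vol$spacing, origin = vol$origin + shift)
}
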