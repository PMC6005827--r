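#' @title Synthetic angiogram phantoms with analytic ground truth
#'
#' @description Phantoms emulate contrast volumes in which the vessel lumen is
#' bright over a dark background, with a finite-width intensity transition at
#' the wall and optional additive Gaussian noise. Every phantom returns both
#' the voxelized [intensity_volume()] and a `phantom_truth` object carrying the
#' analytic inside-lumen predicate, the signed distance to the lumen surface
#' (mm, positive inside) and, where closed-form, the analytic lumen volume.
#'
#' The intensity model is
#' \deqn{I(x) = I_{bg} + (I_{lumen} - I_{bg}) \, s(sd(x)/w),}
#' where `s` is a clamped linear ramp from 0 at `sd = -w` to 1 at `sd = +w`
#' (a step function when `w = 0`). The half-way iso-level
#' `I0 = (I_lumen + I_bg)/2` therefore lies exactly on the analytic surface
#' when the volume is noise-free, which is what makes the sub-voxel wall
#' position recoverable by linear interpolation of the level-set field.
#'
#' @name phantoms
NULL

ramp01 <- function(q) pmin(1, pmax(0, (q + 1) / 2))

phantom_intensity <- function(sd, I_lumen, I_bg, wall_width) {
  s <- if (wall_width > 0) ramp01(sd / wall_width) else (sd > 0) + 0.5 * (sd == 0)
  I_bg + (I_lumen - I_bg) * s
}

# Evaluate fn while the global RNG is deterministically seeded; restores state.
with_phantom_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

grid_points <- function(dims, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  cbind(
    rep(xs, times = dims[2] * dims[3]),
    rep(rep(ys, each = dims[1]), times = dims[3]),
    rep(zs, each = dims[1] * dims[2])
  )
}

phantom_truth <- function(sdist, params, volume_mm3 = NA_real_, extra = list()) {
  structure(
    c(list(
      sdist = sdist,
      inside = function(pts) sdist(pts) > 0,
      params = params,
      volume_mm3 = volume_mm3
    ), extra),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>", x$params$kind, "\n")
  if (is.finite(x$volume_mm3))
    cat(sprintf("  analytic lumen volume: %.4g mm^3\n", x$volume_mm3))
  invisible(x)
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# signed distance (mm, positive inside) to an infinite circular cylinder
sd_tube <- function(pts, center, axis, radius) {
  q <- sweep(pts, 2, center)
  t <- as.numeric(q %*% axis)
  perp2 <- rowSums(q^2) - t^2
  radius - sqrt(pmax(perp2, 0))
}

sd_sphere <- function(pts, center, radius) {
  q <- sweep(pts, 2, center)
  radius - sqrt(rowSums(q^2))
}

build_phantom <- function(dims, spacing, sdist, I_lumen, I_bg, wall_width,
                          noise_sd, seed) {
  pts <- grid_points(dims, spacing)
  sd <- sdist(pts)
  if (!any(sd > 0)) stop("lumen does not intersect the domain")
  I <- phantom_intensity(sd, I_lumen, I_bg, wall_width)
  if (noise_sd > 0)
    I <- I + with_phantom_seed(seed, function()
      stats::rnorm(length(I), sd = noise_sd))
  intensity_volume(array(I, dims), spacing = spacing)
}

#' Straight-tube phantom
#'
#' A bright circular cylinder over a dark background. The default tube axis is
#' z and the default centre is slightly offset from the lattice symmetry
#' planes, which avoids artificially symmetric voxelizations.
#'
#' @param dims integer length-3 voxel counts.
#' @param spacing voxel size (mm), length 3.
#' @param radius tube radius (mm); must be at least `3 * max(spacing)`.
#' @param axis tube axis: `"x"`, `"y"`, `"z"` (optionally signed, e.g. `"-z"`)
#'   or a length-3 vector, normalized internally.
#' @param center point on the tube axis (mm); default the domain centre offset
#'   by `(0.13, 0.37, 0) * spacing`.
#' @param I_lumen,I_bg lumen and background intensities (scanner units).
#' @param wall_width half-width `w` of the linear intensity ramp at the wall
#'   (mm); `0` gives a hard step.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise.
#' @param seed integer RNG seed used for the noise; the phantom is
#'   deterministic given `(parameters, seed)`.
#' @return `list(volume, truth)` with an [intensity_volume()] and a
#'   `phantom_truth`.
#' @examples
#' ph <- straight_tube_phantom(c(24, 24, 16), rep(0.25, 3), radius = 1.2)
#' ph$truth$params$radius
#' @export
straight_tube_phantom <- function(dims, spacing, radius, axis = "z",
                                  center = NULL,
                                  I_lumen = 1000, I_bg = 0, wall_width = 0,
                                  noise_sd = 0, seed = NULL) {
  spacing <- as.numeric(spacing)
  a <- parse_axis(axis)
  if (radius < 3 * max(spacing))
    stop("tube radius must be at least 3 voxels (3 * max(spacing))")
  if (is.null(center))
    center <- dims * spacing / 2 + c(0.13, 0.37, 0) * spacing
  sdist <- function(pts) sd_tube(pts, center, a, radius)
  vol <- build_phantom(dims, spacing, sdist, I_lumen, I_bg, wall_width,
                       noise_sd, seed)
  L <- tube_length_in_box(center, a, dims * spacing)
  truth <- phantom_truth(
    sdist,
    params = list(kind = "straight_tube", radius = radius, axis = a,
                  center = center, I_lumen = I_lumen, I_bg = I_bg,
                  wall_width = wall_width),
    volume_mm3 = pi * radius^2 * L
  )
  list(volume = vol, truth = truth)
}

parse_axis <- function(axis) {
  if (is.character(axis)) {
    sgn <- if (startsWith(axis, "-")) -1 else 1
    ax <- sub("^[+-]", "", axis)
    v <- switch(ax, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                stop("unknown axis label: ", axis))
    sgn * v
  } else normalize(as.numeric(axis))
}

# chord length of an infinite line (point p, unit dir a) inside [0, ext]^3
tube_length_in_box <- function(p, a, ext) {
  t0 <- -Inf; t1 <- Inf
  for (m in 1:3) {
    if (abs(a[m]) < 1e-14) {
      if (p[m] < 0 || p[m] > ext[m]) return(0)
    } else {
      tt <- sort(c((0 - p[m]) / a[m], (ext[m] - p[m]) / a[m]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  max(t1 - t0, 0)
}

#' Curved-tube phantom
#'
#' A torus-segment lumen (constant tube radius around a circular-arc
#' centerline in the x-z plane) with both ends extended by straight tangent
#' rays so the tube crosses the domain. `arc_span = 0` degenerates exactly to
#' a straight tube along z. Exercises flow through a curved upstream vessel.
#'
#' @inheritParams straight_tube_phantom
#' @param torus_major_R radius of the centerline arc (mm);
#'   must exceed `tube_radius`.
#' @param tube_radius tube (minor) radius in mm.
#' @param arc_span arc angle in degrees, symmetric about the through-point.
#' @param center point where the arc crosses, tangent to z (mm).
#' @return `list(volume, truth)`.
#' @export
curved_tube_phantom <- function(dims, spacing, torus_major_R, tube_radius,
                                arc_span, center = NULL,
                                I_lumen = 1000, I_bg = 0, wall_width = 0,
                                noise_sd = 0, seed = NULL) {
  spacing <- as.numeric(spacing)
  if (torus_major_R <= tube_radius)
    stop("torus_major_R must exceed tube_radius")
  if (tube_radius < 3 * max(spacing))
    stop("tube radius must be at least 3 voxels")
  if (is.null(center))
    center <- dims * spacing / 2 + c(0.13, 0.37, 0) * spacing
  half <- arc_span / 2 * pi / 180
  C <- center + c(torus_major_R, 0, 0) # arc centre; arc bulges toward -x
  sdist <- function(pts) tube_radius - dist_to_arc_line(pts, C, torus_major_R, half)
  vol <- build_phantom(dims, spacing, sdist, I_lumen, I_bg, wall_width,
                       noise_sd, seed)
  truth <- phantom_truth(
    sdist,
    params = list(kind = "curved_tube", torus_major_R = torus_major_R,
                  tube_radius = tube_radius, arc_span = arc_span,
                  center = center, arc_center = C, I_lumen = I_lumen,
                  I_bg = I_bg, wall_width = wall_width),
    extra = list(centerline_point = function(theta)
      C + torus_major_R * c(-cos(theta), 0, sin(theta)))
  )
  list(volume = vol, truth = truth)
}

# distance from pts to {arc of radius Rm about C in the x-z plane,
# theta in [-half, half] measured from the -x direction} extended by
# straight tangent rays at both ends
dist_to_arc_line <- function(pts, C, Rm, half) {
  q <- sweep(pts, 2, C)
  theta <- atan2(q[, 3], -q[, 1])
  rho <- sqrt(q[, 1]^2 + q[, 3]^2)
  d_arc <- sqrt((rho - Rm)^2 + q[, 2]^2)
  on_arc <- abs(theta) <= half
  d <- ifelse(on_arc, d_arc, Inf)
  for (s in c(-1, 1)) {
    th <- s * half
    E <- C + Rm * c(-cos(th), 0, sin(th))
    Tdir <- s * normalize(c(sin(th), 0, cos(th))) # outward unit tangent
    e <- sweep(pts, 2, E)
    t <- pmax(e %*% Tdir, 0)
    d_ray <- sqrt(rowSums((e - t %*% t(Tdir))^2))
    d <- pmin(d, d_ray)
  }
  d
}

#' Sidewall-aneurysm phantom
#'
#' Union of a straight tube along z (the parent vessel) and a spherical sac
#' attached to its side wall. The truth carries, in addition to the lumen
#' predicate, an aneurysm-region predicate (inside the sphere, outside the
#' tube) used by metric tests, and an approximate closed-form union volume in
#' which the sphere-tube overlap is treated as a spherical cap cut by the
#' locally planar wall.
#'
#' @inheritParams straight_tube_phantom
#' @param radius parent tube radius (mm).
#' @param sac_center centre of the spherical sac (mm); default places the sac
#'   on the +x side of the default tube. Must intersect the tube wall so that
#'   the lumen stays one connected component.
#' @param sac_radius sac radius (mm).
#' @return `list(volume, truth)`; `truth$aneurysm(pts)` is the sac predicate.
#' @export
sidewall_aneurysm_phantom <- function(dims, spacing, radius, sac_center = NULL,
                                      sac_radius = NULL, center = NULL,
                                      I_lumen = 1000, I_bg = 0, wall_width = 0,
                                      noise_sd = 0, seed = NULL) {
  spacing <- as.numeric(spacing)
  if (radius < 3 * max(spacing))
    stop("tube radius must be at least 3 voxels")
  if (is.null(center))
    center <- dims * spacing / 2 + c(0.13, 0.37, 0) * spacing
  if (is.null(sac_radius)) sac_radius <- 0.9 * radius
  if (is.null(sac_center))
    sac_center <- center + c(radius + 0.6 * sac_radius, 0, 0)
  a <- c(0, 0, 1)
  D <- sqrt(sum((sac_center - center)[1:2]^2)) # distance of sac centre to axis
  if (D - sac_radius >= radius)
    stop("sac does not intersect the tube wall; lumen would be disconnected")
  ext <- dims * spacing
  if (any(sac_center - sac_radius < 0) || any(sac_center + sac_radius > ext))
    warning("sac extends beyond the domain; analytic union volume will not ",
            "match the voxelized lumen")
  sd_t <- function(pts) sd_tube(pts, center, a, radius)
  sd_s <- function(pts) sd_sphere(pts, sac_center, sac_radius)
  sdist <- function(pts) pmax(sd_t(pts), sd_s(pts))
  vol <- build_phantom(dims, spacing, sdist, I_lumen, I_bg, wall_width,
                       noise_sd, seed)
  # planar-wall approximation of the overlap: spherical cap beyond the plane
  # at distance (D - radius) from the sac centre toward the axis
  h <- D - radius
  cap_a <- max(sac_radius - h, 0)            # cap height inside the tube
  v_cap <- pi * cap_a^2 * (3 * sac_radius - cap_a) / 3
  L <- dims[3] * spacing[3]
  v_union <- pi * radius^2 * L + 4 / 3 * pi * sac_radius^3 - v_cap
  truth <- phantom_truth(
    sdist,
    params = list(kind = "sidewall_aneurysm", radius = radius,
                  sac_center = sac_center, sac_radius = sac_radius,
                  center = center, axis = a, I_lumen = I_lumen, I_bg = I_bg,
                  wall_width = wall_width),
    volume_mm3 = v_union,
    extra = list(aneurysm = function(pts) sd_s(pts) > 0 & sd_t(pts) <= 0)
  )
  list(volume = vol, truth = truth)
}

#' Two disconnected vessel phantom
#'
#' Two parallel straight tubes along z with disjoint lumens, both above
#' threshold. Downstream segmentation seeded in one tube must exclude all
#' voxels of the other (connectivity clean-up); the truth labels each point by
#' component id (0 background, 1, 2).
#'
#' @inheritParams straight_tube_phantom
#' @param radius1,radius2 tube radii (mm).
#' @param separation distance between the two axes (mm); must exceed
#'   `radius1 + radius2 + 2 * wall_width + max(spacing)` so the voxelized
#'   components stay face-disconnected.
#' @return `list(volume, truth)`; `truth$component(pts)` gives labels 0/1/2.
#' @export
two_vessel_phantom <- function(dims, spacing, radius1, radius2,
                               separation = NULL,
                               I_lumen = 1000, I_bg = 0, wall_width = 0,
                               noise_sd = 0, seed = NULL) {
  spacing <- as.numeric(spacing)
  if (min(radius1, radius2) < 3 * max(spacing))
    stop("tube radii must be at least 3 voxels")
  ext <- dims * spacing
  if (is.null(separation))
    separation <- radius1 + radius2 + 2 * wall_width + 3 * max(spacing)
  min_sep <- radius1 + radius2 + 2 * wall_width + max(spacing)
  if (separation < min_sep)
    stop("tubes overlap or touch: separation must exceed ", signif(min_sep, 4))
  mid <- ext / 2 + c(0.13, 0.37, 0) * spacing
  c1 <- mid + c(-separation / 2, 0, 0)
  c2 <- mid + c(+separation / 2, 0, 0)
  a <- c(0, 0, 1)
  sd1 <- function(pts) sd_tube(pts, c1, a, radius1)
  sd2 <- function(pts) sd_tube(pts, c2, a, radius2)
  sdist <- function(pts) pmax(sd1(pts), sd2(pts))
  vol <- build_phantom(dims, spacing, sdist, I_lumen, I_bg, wall_width,
                       noise_sd, seed)
  truth <- phantom_truth(
    sdist,
    params = list(kind = "two_vessel", radius1 = radius1, radius2 = radius2,
                  center1 = c1, center2 = c2, axis = a, I_lumen = I_lumen,
                  I_bg = I_bg, wall_width = wall_width),
    volume_mm3 = pi * (radius1^2 + radius2^2) * ext[3],
    extra = list(component = function(pts)
      as.integer(ifelse(sd1(pts) > 0, 1L, ifelse(sd2(pts) > 0, 2L, 0L))))
  )
  list(volume = vol, truth = truth)
}
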