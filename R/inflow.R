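#' Bessel function J0 of a complex argument
#'
#' Power series \eqn{J_0(z) = \sum_k (-1)^k (z^2/4)^k / (k!)^2}, adequate to
#' full double precision for the argument magnitudes that arise in
#' physiological Womersley profiles (`|z|` up to roughly 25).
#'
#' @param z complex vector.
#' @return complex vector of `J0(z)`.
#' @keywords internal
besselJ0_complex <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -z^2 / 4
  for (k in 1:80) {
    term <- term * q / k^2
    out <- out + term
    if (max(abs(term)) < 1e-18 * max(abs(out))) break
  }
  out
}

#' Oscillatory pipe-flow (Womersley) radial mode shape
#'
#' The classical rigid-tube solution for fully developed oscillatory flow,
#' normalized so the shape equals 1 at the centerline:
#' \deqn{f(\xi) = \frac{1 - J_0(i^{3/2} Wo\, \xi)/J_0(i^{3/2} Wo)}
#'                   {1 - 1/J_0(i^{3/2} Wo)},}
#' with `xi = r/R` the normalized radius and `Wo` the Womersley number. The
#' no-slip rim value `f(1)` is exactly 0 for every `Wo`. As `Wo -> 0` the
#' shape tends to the quasi-steady parabola `1 - xi^2`.
#'
#' @param xi normalized radius in `[0, 1]` (vectorized).
#' @param Wo Womersley number (`> 0`).
#' @return complex vector; the physical velocity of a mode with complex
#'   centerline amplitude `A` at circular frequency `w` is
#'   `Re(A * f(xi) * exp(1i * w * t))`.
#' @export
womersley_shape <- function(xi, Wo) {
  if (Wo <= 0) stop("Womersley number must be positive")
  a <- complex(modulus = 1, argument = 3 * pi / 4) * Wo  # i^{3/2} Wo
  J0a <- besselJ0_complex(a)
  num <- 1 - besselJ0_complex(a * xi) / J0a
  num / (1 - 1 / J0a)
}

#' Womersley number of a vessel
#'
#' `Wo = R * sqrt(rho * 2 * pi * f0 / mu)`.
#'
#' @param R vessel radius (m).
#' @param f0 heart rate (Hz).
#' @param rho blood density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @return dimensionless Womersley number.
#' @export
womersley_number <- function(R, f0, rho = 1060, mu = 0.0035) {
  R * sqrt(rho * 2 * pi * f0 / mu)
}

#' Steady parabolic inflow profile on a boundary patch
#'
#' Fully developed profile aligned with the local centerline tangent,
#' \deqn{U = U_0 [1 - (|R'|/R'_{max})^2] s,}
#' evaluated at every patch voxel from the in-plane radius vectors.
#'
#' @param frame a `centerline_frame` with in-plane radii (see
#'   [inplane_radius()]; computed here if absent).
#' @param U0 peak (centerline) steady velocity, m/s.
#' @return An `inflow_profile`: `frame`, `U0`, per-voxel steady speeds
#'   `u_steady` (m/s), `velocity(t)` function returning an n x 3 matrix of
#'   velocity vectors (constant in `t` for a steady profile), and `steady`
#'   flag.
#' @export
parabolic_profile <- function(frame, U0) {
  stopifnot(inherits(frame, "centerline_frame"))
  if (U0 <= 0) stop("U0 must be positive")
  if (is.null(frame$Rprime_max)) frame <- inplane_radius(frame)
  if (nrow(frame$patch$voxels) < 2L || frame$Rprime_max <= 0)
    stop("degenerate inflow patch (single voxel)")
  xi <- frame$Rprime_norm / frame$Rprime_max
  u_steady <- U0 * (1 - xi^2)
  prof <- structure(
    list(frame = frame, U0 = U0, xi = xi, u_steady = u_steady,
         f0 = NULL, harmonics = NULL, Wo = NULL, steady = TRUE),
    class = "inflow_profile"
  )
  prof$velocity <- function(t = 0) inflow_speed(prof, t) %*% t(frame$tangent)
  prof
}

#' Superpose oscillatory Womersley harmonics on an inflow profile
#'
#' Extends a steady [parabolic_profile()] with fully developed oscillatory
#' modes at harmonics of the heart rate `f0`. Harmonic `h` has Womersley
#' number `Wo * sqrt(h)` and centerline velocity
#' `amp_h * cos(2 pi h f0 t + phase_h)`; its radial shape is the rigid-tube
#' solution [womersley_shape()]. The rim velocity is exactly zero at all
#' times and the zero-mean harmonics leave the period average equal to the
#' steady part.
#'
#' @param profile an `inflow_profile`.
#' @param Wo Womersley number of the fundamental (at `f0`); see
#'   [womersley_number()].
#' @param f0 heart rate, Hz.
#' @param harmonics matrix (or list of pairs) with columns
#'   `(amplitude m/s, phase degrees)`; row `h` is the harmonic at `h * f0`.
#' @return The profile with pulsatile fields set (`steady = FALSE`).
#' @export
womersley_profile <- function(profile, Wo, f0, harmonics) {
  stopifnot(inherits(profile, "inflow_profile"))
  if (Wo <= 0 || f0 <= 0) stop("Wo and f0 must be positive")
  if (is.list(harmonics)) harmonics <- do.call(rbind, harmonics)
  harmonics <- matrix(as.numeric(harmonics), ncol = 2)
  if (nrow(harmonics) == 0) stop("harmonics must be non-empty for a pulsatile run")
  profile$Wo <- Wo
  profile$f0 <- f0
  profile$harmonics <- harmonics
  profile$steady <- FALSE
  # precompute complex per-voxel shapes per harmonic
  profile$mode_shapes <- lapply(seq_len(nrow(harmonics)), function(h) {
    womersley_shape(profile$xi, Wo * sqrt(h))
  })
  prof <- profile
  prof$velocity <- function(t = 0)
    inflow_speed(prof, t) %*% t(prof$frame$tangent)
  prof
}

# per-voxel signed speed along the tangent at time t
inflow_speed <- function(profile, t) {
  u <- profile$u_steady
  if (!is.null(profile$harmonics)) {
    for (h in seq_len(nrow(profile$harmonics))) {
      amp <- profile$harmonics[h, 1]
      ph <- profile$harmonics[h, 2] * pi / 180
      A <- amp * exp(1i * ph)
      w <- 2 * pi * h * profile$f0
      u <- u + Re(A * profile$mode_shapes[[h]] * exp(1i * w * t))
    }
  }
  u
}

#' Sample an inflow profile onto the boundary faces of the flow domain
#'
#' Evaluates the profile's velocity vectors at the patch voxels and reports
#' the imposed volumetric flux through the ROI face: the face-normal velocity
#' component summed over patch voxels times the face area of a voxel. The
#' normal components live on the boundary face plane; tangential components
#' are imposed at their staggered locations by the solver's boundary
#' treatment.
#'
#' @param profile an `inflow_profile`.
#' @param t time (s).
#' @return list with `velocity` (n x 3, m/s, rows follow the patch voxels),
#'   `normal_flux` (m^3/s, positive into the domain), `face_area` (m^2).
#' @export
map_profile_to_faces <- function(profile, t = 0) {
  stopifnot(inherits(profile, "inflow_profile"))
  fr <- profile$frame
  vel <- profile$velocity(t)
  ax <- fr$axis
  inward <- if (fr$patch$slice_index == 1L) 1 else -1
  sp_m <- fr$spacing * 1e-3
  area <- prod(sp_m[-ax])
  flux <- sum(vel[, ax]) * area * inward
  list(velocity = vel, normal_flux = flux, face_area = area)
}
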