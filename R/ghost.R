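#' Ghost-fluid wall closure at a cell face
#'
#' Computes the boundary velocity `U_BC` imposed at a point half a grid
#' spacing from the nearest fluid velocity sample `u_near`, for a stationary
#' no-slip wall located a distance `d` from `u_near` on the far side of that
#' point. Two branches are used, switching continuously at `d = delta/2`
#' (both give `U_BC = 0` there):
#'
#' * `d < delta/2` (wall between the sample and the face): linear
#'   interpolation through the wall zero,
#'   `U_BC = u_near * (1 - delta / (2 d))`.
#' * `d >= delta/2` (wall beyond the face): the ghost-fluid construction --
#'   mirror the ghost point across the wall, interpolate the image-point
#'   velocity from `u_near` and the next fluid sample `u_next`, flip its sign,
#'   and average with `u_near` -- whose closed form is
#'   `U_BC = (u_near - u_next) * (delta/2 - d) / delta`.
#'
#' Both branches return the exact face value for any velocity profile that is
#' linear in the wall-normal coordinate and vanishes at the wall: this is the
#' sharp-interface property of the method. `d` is clamped below at
#' `0.05 * delta`; below the clamp the wall velocity (zero) is returned.
#'
#' @param u_near velocity at the first fluid sample, distance `d` from the
#'   wall (m/s). Vectorized.
#' @param u_next velocity at the second fluid sample, one spacing further into
#'   the fluid; only used by the `d >= delta/2` branch. May be `NA` where
#'   unavailable, in which case the linear-interpolation branch is used for
#'   all `d`.
#' @param d distance from the `u_near` sample to the wall, `0 < d <= 1.5 delta`.
#' @param delta grid spacing in the wall-normal direction (m).
#' @return `U_BC`, same length as `u_near`.
#' @examples
#' ghost_face_velocity(1, 2, d = 0.75, delta = 1) # (1-2)(0.5-0.75)/1 = 0.25
#' ghost_face_velocity(1, 0, d = 0.25, delta = 1) # 1*(1-2) = -1
#' @export
ghost_face_velocity <- function(u_near, u_next, d, delta) {
  n <- max(length(u_near), length(d))
  u_near <- rep_len(u_near, n)
  u_next <- rep_len(u_next, n)
  d <- rep_len(d, n)
  if (any(d <= 0, na.rm = TRUE)) stop("wall distance d must be positive")
  dmin <- 0.05 * delta
  dc <- pmax(d, dmin)
  low <- dc < delta / 2 | is.na(u_next)
  ubc <- ifelse(low,
                u_near * (1 - delta / (2 * dc)),
                (u_near - u_next) * (delta / 2 - dc) / delta)
  ifelse(d < dmin, 0, ubc)
}

#' Mirrored ghost-point velocity one spacing past a fluid sample
#'
#' The ghost-fluid value at a grid point one full spacing `delta` from
#' `u_near` toward the wall. The ghost point is mirrored across the wall
#' (distance `d` from `u_near`, `0 < d <= delta`); the image velocity is
#' linearly interpolated/extrapolated from `u_near` and `u_next` and its sign
#' flipped so the velocity interpolates to zero at the wall. On the staggered
#' grid this closure supplies parallel-face neighbor values, while
#' [ghost_face_velocity()] (its average with `u_near`) supplies half-spacing
#' face values; both are exact for linear profiles vanishing at the wall.
#'
#' @inheritParams ghost_face_velocity
#' @param d distance from `u_near` to the wall, in `(0, delta]`.
#' @return ghost velocity, same length as `u_near`.
#' @export
ghost_point_velocity <- function(u_near, u_next, d, delta) {
  n <- max(length(u_near), length(d))
  u_near <- rep_len(u_near, n)
  u_next <- rep_len(u_next, n)
  d <- rep_len(d, n)
  dmin <- 0.05 * delta
  dc <- pmin(pmax(d, dmin), delta)
  u_im <- ifelse(is.na(u_next),
                 u_near * (delta - dc) / dc,
                 u_near + (u_near - u_next) * (2 * dc - delta) / delta)
  ifelse(d < dmin, -u_near, -u_im)
}

# chain coefficients (c_near, c_next) such that the mirrored ghost value is
# c_near * u_near + c_next * u_next; used to fold wall closures into the
# implicit operators
ghost_point_coefs <- function(d, delta, has_next) {
  dmin <- 0.05 * delta
  dc <- pmin(pmax(d, dmin), delta)
  # without a second sample the linear-through-wall closure is clamped to
  # d >= delta/3 to keep the reflection coefficient bounded (|c| <= 2)
  dc1 <- pmax(dc, delta / 3)
  cn <- ifelse(has_next, -(1 + (2 * dc - delta) / delta), -(delta - dc1) / dc1)
  cx <- ifelse(has_next, (2 * dc - delta) / delta, 0)
  cn <- ifelse(d < dmin, -1, cn)
  cx <- ifelse(d < dmin, 0, cx)
  cbind(cn, cx)
}
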