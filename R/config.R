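#' Pipeline run configuration
#'
#' Validated settings for a full image-to-hemodynamics run. The JSON layout
#' mirrors this function's arguments; [load_config()] reads a JSON document
#' and applies the same validation and defaults. Unknown keys are rejected to
#' catch typos.
#'
#' @param volume path to the input NIfTI volume (ignored when `phantom` is
#'   given).
#' @param phantom optional list describing a synthetic input, e.g.
#'   `list(kind = "straight_tube", dims = c(24,24,32), spacing = rep(0.25,3),
#'   radius = 1.2)`; `kind` selects the phantom generator and the remaining
#'   entries are passed through to it.
#' @param roi optional list with `i`, `j`, `k` inclusive index ranges
#'   (1-based); default: the full volume.
#' @param seed integer length-3 seed voxel for region growing (1-based,
#'   inside the ROI).
#' @param I0 threshold intensity (scanner units).
#' @param grad_max optional region-growing gradient cap.
#' @param inflow_face one of `"imin"`, `"imax"`, `"jmin"`, `"jmax"`,
#'   `"kmin"`, `"kmax"`.
#' @param U0 peak inflow velocity (m/s), `> 0`.
#' @param f0 heart rate (Hz) for pulsatile runs.
#' @param harmonics matrix/list of `(amplitude, phase_deg)` rows for
#'   pulsatile harmonics of `f0`; `NULL` for a steady run.
#' @param steady logical; steady parabolic inflow (default `TRUE`).
#' @param rho blood density (kg/m^3), default 1060.
#' @param mu dynamic viscosity (Pa s), default 0.0035.
#' @param dt fixed solver time step (s); `NULL` selects from `cfl`.
#' @param cfl CFL number used to pick `dt`, default 0.5.
#' @param poisson_tol pressure-projection divergence bound.
#' @param steady_tol steady-state detection tolerance.
#' @param max_time simulated end time (s).
#' @param smooth logical; apply the level-set low-pass filter (default TRUE).
#' @param centerline_depth slices used for the centerline tangent.
#' @param rng_seed RNG seed for phantom noise.
#' @param output_dir directory for pipeline outputs.
#' @return A validated `pipeline_config` list with defaults applied.
#' @export
pipeline_config <- function(volume = NULL, phantom = NULL, roi = NULL,
                            seed, I0, grad_max = NULL, inflow_face,
                            U0, f0 = NULL, harmonics = NULL, steady = TRUE,
                            rho = 1060, mu = 0.0035, dt = NULL, cfl = 0.5,
                            poisson_tol = 1e-8, steady_tol = 1e-3,
                            max_time = 1, smooth = TRUE,
                            centerline_depth = 4L, rng_seed = 1L,
                            output_dir = ".") {
  if (is.null(volume) && is.null(phantom))
    stop("config needs either a volume path or a phantom spec")
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(is.na(seed)) || any(seed < 1L))
    stop("seed must be three positive integers")
  if (!is.numeric(I0) || length(I0) != 1L) stop("I0 must be a number")
  faces <- c("imin", "imax", "jmin", "jmax", "kmin", "kmax")
  if (!inflow_face %in% faces)
    stop("inflow_face must be one of ", paste(faces, collapse = ", "))
  if (!is.numeric(U0) || U0 <= 0) stop("U0 must be positive")
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  if (cfl <= 0) stop("cfl must be positive")
  if (!steady && (is.null(f0) || is.null(harmonics)))
    stop("pulsatile runs need f0 and harmonics")
  if (!is.null(f0) && f0 <= 0) stop("f0 must be positive")
  if (!is.null(roi)) {
    if (!all(c("i", "j", "k") %in% names(roi)))
      stop("roi must have i, j, k ranges")
    roi <- roi_box(roi$i, roi$j, roi$k)
  }
  structure(list(
    volume = volume, phantom = phantom, roi = roi, seed = seed, I0 = I0,
    grad_max = grad_max, inflow_face = inflow_face, U0 = U0, f0 = f0,
    harmonics = harmonics, steady = isTRUE(steady), rho = rho, mu = mu,
    dt = dt, cfl = cfl, poisson_tol = poisson_tol, steady_tol = steady_tol,
    max_time = max_time, smooth = isTRUE(smooth),
    centerline_depth = as.integer(centerline_depth),
    rng_seed = as.integer(rng_seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration from JSON
#'
#' Reads a JSON document whose keys mirror the arguments of
#' [pipeline_config()], rejects unknown keys, validates ranges and applies
#' the documented defaults (`rho = 1060`, `mu = 0.0035`, `cfl = 0.5`, ...).
#' Parsing is deterministic and key order does not matter.
#'
#' @param path path to a JSON file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  req <- c("seed", "I0", "inflow_face", "U0")
  missing <- setdiff(req, names(doc))
  if (length(missing))
    stop("missing required config keys: ", paste(missing, collapse = ", "))
  if (!is.null(doc$harmonics))
    doc$harmonics <- matrix(as.numeric(unlist(doc$harmonics)), ncol = 2,
                            byrow = !is.matrix(doc$harmonics))
  do.call(pipeline_config, doc)
}

#' @export
print.pipeline_config <- function(x, ...) {
  src <- if (!is.null(x$phantom)) paste0("phantom:", x$phantom$kind)
  else x$volume
  cat(sprintf(
    "<pipeline_config> %s, I0 = %.4g, seed (%s), inflow %s, U0 = %.3g m/s (%s)\n",
    src, x$I0, paste(x$seed, collapse = ","), x$inflow_face, x$U0,
    if (x$steady) "steady" else "pulsatile"))
  invisible(x)
}
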