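#' Scanner geometry for the gating temporal budget
#'
#' Bundles the acquisition parameters that determine how long a voxel at the
#' edge of the field of view stays illuminated during a low-pitch helical
#' scan, and hence how wide the temporal gating window of each respiratory
#' phase must be.
#'
#' @param source_isocenter_distance Source to isocenter distance (mm).
#' @param fov Reconstruction field of view diameter (mm); must be smaller
#'   than twice the source-isocenter distance.
#' @param collimation Longitudinal beam collimation at isocenter (mm).
#' @param rotation_time Gantry rotation time (s).
#' @param pitch Unitless helical pitch factor (couch travel per rotation /
#'   collimation). Zero means a stationary couch.
#' @param projections_per_rotation Number of projections acquired per full
#'   gantry rotation.
#'
#' @return An object of class `scanner_geometry`.
#' @examples
#' geom <- scanner_geometry(570, fov = 500, collimation = 24,
#'                          rotation_time = 0.5, pitch = 0.1)
#' visibility_length(geom)
#' max_breathing_period(geom)
#' @export
scanner_geometry <- function(source_isocenter_distance = 570,
                             fov = 500,
                             collimation = 24,
                             rotation_time = 0.5,
                             pitch = 0.1,
                             projections_per_rotation = 720L) {
  stopifnot(
    is.numeric(source_isocenter_distance), source_isocenter_distance > 0,
    is.numeric(fov), fov > 0,
    is.numeric(collimation), collimation > 0,
    is.numeric(rotation_time), rotation_time > 0,
    is.numeric(pitch), pitch >= 0,
    projections_per_rotation >= 2
  )
  if (fov >= 2 * source_isocenter_distance) {
    stop("fov must be smaller than twice the source-isocenter distance ",
         "(negative visibility length is meaningless)")
  }
  structure(
    list(
      source_isocenter_distance = as.numeric(source_isocenter_distance),
      fov = as.numeric(fov),
      collimation = as.numeric(collimation),
      rotation_time = as.numeric(rotation_time),
      pitch = as.numeric(pitch),
      projections_per_rotation = as.integer(projections_per_rotation)
    ),
    class = "scanner_geometry"
  )
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("Scanner geometry\n")
  cat(sprintf("  source-isocenter : %g mm\n", x$source_isocenter_distance))
  cat(sprintf("  FOV              : %g mm\n", x$fov))
  cat(sprintf("  collimation      : %g mm\n", x$collimation))
  cat(sprintf("  rotation time    : %g s\n", x$rotation_time))
  cat(sprintf("  pitch            : %g\n", x$pitch))
  cat(sprintf("  projections/rot  : %d\n", x$projections_per_rotation))
  invisible(x)
}

#' Visibility length at the edge of the field of view
#'
#' Length along the couch axis over which a voxel at the FOV edge remains
#' inside the collimated beam: `Zm = (Rs - FOV/2) * COLL / Rs`. It shrinks as
#' the FOV grows (the beam diverges from a point source) and is linear in the
#' collimation.
#'
#' @param geom A [scanner_geometry()].
#' @return Visibility length in mm.
#' @export
visibility_length <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  rs <- geom$source_isocenter_distance
  (rs - geom$fov / 2) * geom$collimation / rs
}

#' Couch velocity
#'
#' `V = pitch * collimation / rotation_time` (mm/s).
#'
#' @inheritParams visibility_length
#' @return Couch velocity in mm/s.
#' @export
couch_velocity <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  geom$pitch * geom$collimation / geom$rotation_time
}

#' Transit time of an edge voxel through the beam
#'
#' Time that a voxel at the edge of the FOV remains illuminated,
#' `TT = Zm / V`. Algebraically identical to the largest breathing period for
#' which every voxel is seen during a full respiratory cycle
#' ([max_breathing_period()]).
#'
#' @inheritParams visibility_length
#' @return Transit time in seconds.
#' @export
transit_time <- function(geom) {
  v <- couch_velocity(geom)
  if (v <= 0) stop("static couch: transit time is unbounded (pitch = 0)")
  visibility_length(geom) / v
}

#' Largest fully illuminated breathing period
#'
#' Upper bound on the breathing period such that every voxel stays inside the
#' beam for a complete respiratory cycle:
#' `BP <= (Rs - FOV/2)/Rs * RT / pitch`. Breathing slower than this (longer
#' period) forces the reconstruction to widen its temporal gate.
#'
#' @inheritParams visibility_length
#' @return The bound in seconds.
#' @export
max_breathing_period <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  if (geom$pitch <= 0) stop("pitch = 0: every breathing period is admissible (unbounded)")
  rs <- geom$source_isocenter_distance
  (rs - geom$fov / 2) / rs * geom$rotation_time / geom$pitch
}

#' Largest admissible pitch for a given breathing period
#'
#' The same full-illumination condition solved for the pitch factor:
#' `pitch <= (1 - FOV/(2 Rs)) * RT / BP`. Plugging
#' [max_breathing_period()] back in recovers the geometry's own pitch.
#'
#' @inheritParams visibility_length
#' @param breathing_period Breathing period in seconds.
#' @return The pitch bound (unitless).
#' @export
max_pitch <- function(geom, breathing_period) {
  stopifnot(inherits(geom, "scanner_geometry"),
            is.numeric(breathing_period), breathing_period > 0)
  rs <- geom$source_isocenter_distance
  (1 - geom$fov / (2 * rs)) * geom$rotation_time / breathing_period
}

#' Temporal gating-window widening
#'
#' When the breathing period exceeds [max_breathing_period()] the
#' reconstruction must widen its temporal gate by
#' `Tw = BP - RT/pitch * (1 - FOV/(2 Rs))` seconds so that edge voxels still
#' receive the minimum half-rotation of projections. When the condition is
#' satisfied the widening is zero (clamped: negative widening is unphysical).
#'
#' @inheritParams max_pitch
#' @return Widening in seconds (`>= 0`); exactly 0 when the breathing-period
#'   condition holds.
#' @export
window_widening <- function(geom, breathing_period) {
  stopifnot(inherits(geom, "scanner_geometry"),
            is.numeric(breathing_period), breathing_period > 0)
  if (geom$pitch <= 0) return(0)
  tw <- breathing_period - max_breathing_period(geom)
  max(0, tw)
}

#' Projection count of the temporal gating window
#'
#' Converts the widened temporal gate into a projection count at the
#' scanner's uniform angular sampling rate:
#' `It = ceiling(PPR/2 + Tw * PPR/RT)`, never below the half-rotation
#' minimum of `PPR/2` projections required for parallel-beam completeness.
#'
#' @inheritParams max_pitch
#' @return Integer projection count.
#' @export
window_projection_count <- function(geom, breathing_period) {
  ppr <- geom$projections_per_rotation
  tw <- window_widening(geom, breathing_period)
  it <- as.integer(ceiling(ppr / 2 + tw * ppr / geom$rotation_time))
  max(it, as.integer(ceiling(ppr / 2)))
}

#' Full gating budget for a geometry and breathing period
#'
#' Evaluates the whole temporal budget at once: visibility length, couch
#' velocity, transit time, breathing-period bound, window widening, and the
#' projection counts of the (possibly widened) gating window.
#'
#' @inheritParams max_pitch
#' @return An object of class `gating_budget` with fields
#'   `visibility_length`, `couch_velocity`, `transit_time`,
#'   `max_breathing_period`, `breathing_period`, `condition_satisfied`,
#'   `window_widening`, `window_projection_count`,
#'   `minimum_projection_count`.
#' @export
gating_budget <- function(geom, breathing_period) {
  stopifnot(inherits(geom, "scanner_geometry"),
            is.numeric(breathing_period), breathing_period > 0)
  tw <- window_widening(geom, breathing_period)
  bpmax <- if (geom$pitch > 0) max_breathing_period(geom) else Inf
  structure(
    list(
      geometry = geom,
      breathing_period = breathing_period,
      visibility_length = visibility_length(geom),
      couch_velocity = couch_velocity(geom),
      transit_time = if (geom$pitch > 0) transit_time(geom) else Inf,
      max_breathing_period = bpmax,
      condition_satisfied = breathing_period <= bpmax,
      window_widening = tw,
      window_projection_count = window_projection_count(geom, breathing_period),
      minimum_projection_count =
        as.integer(ceiling(geom$projections_per_rotation / 2))
    ),
    class = "gating_budget"
  )
}

#' @export
print.gating_budget <- function(x, ...) {
  cat("Gating budget\n")
  cat(sprintf("  breathing period    : %.4g s (bound %.4g s; condition %s)\n",
              x$breathing_period, x$max_breathing_period,
              if (x$condition_satisfied) "satisfied" else "violated"))
  cat(sprintf("  visibility length   : %.4g mm\n", x$visibility_length))
  cat(sprintf("  couch velocity      : %.4g mm/s\n", x$couch_velocity))
  cat(sprintf("  window widening Tw  : %.4g s\n", x$window_widening))
  cat(sprintf("  window projections  : %d (minimum %d)\n",
              x$window_projection_count, x$minimum_projection_count))
  invisible(x)
}
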