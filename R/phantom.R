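#' Phantom object (disk or rectangle)
#'
#' One embedded object of the digital phantom: a disk or axis-aligned
#' rectangle of uniform linear attenuation, optionally translated along the
#' superior-inferior (SI, in-plane y) or anterior-posterior (AP, in-plane x)
#' axis by the respiratory waveform.
#'
#' @param shape `"disk"` or `"rectangle"`.
#' @param center Reference-time center `c(x, y)` in mm.
#' @param size Diameter (disk) or edge lengths `c(width, height)`
#'   (rectangle; a scalar gives a square), in mm.
#' @param attenuation Linear attenuation (1/mm).
#' @param motion_axis `"none"`, `"SI"` or `"AP"`.
#' @param excursion Peak-to-peak excursion in mm. The object follows the
#'   waveform displacement scaled by `excursion / amplitude(waveform)`, so
#'   with `excursion` equal to the waveform amplitude it follows the
#'   waveform exactly; 0 means static.
#' @return An object of class `phantom_object`.
#' @export
phantom_object <- function(shape = c("disk", "rectangle"), center = c(0, 0),
                           size = 20, attenuation = 0.019,
                           motion_axis = c("none", "SI", "AP"),
                           excursion = 0) {
  shape <- match.arg(shape)
  motion_axis <- match.arg(motion_axis)
  stopifnot(length(center) == 2, all(size > 0), excursion >= 0)
  if (shape == "rectangle" && length(size) == 1L) size <- c(size, size)
  if (shape == "disk") stopifnot(length(size) == 1L)
  structure(
    list(shape = shape, center = as.numeric(center), size = as.numeric(size),
         attenuation = as.numeric(attenuation), motion_axis = motion_axis,
         excursion = as.numeric(excursion)),
    class = "phantom_object"
  )
}

#' @export
print.phantom_object <- function(x, ...) {
  cat(sprintf("%s at (%g, %g) mm, size %s mm, mu %g/mm, motion %s (%g mm p-p)\n",
              x$shape, x$center[1], x$center[2],
              paste(x$size, collapse = "x"), x$attenuation,
              x$motion_axis, x$excursion))
  invisible(x)
}

#' Generate a respiratory motion waveform
#'
#' Produces the sampled breathing trace that drives both the phantom motion
#' and the retrospective phase sorting: a surrogate signal (the analog of a
#' bellows-belt reading) and a synchronous target displacement in mm.
#' Supported shapes are a sinusoid, a sawtooth (slow linear exhale-like ramp
#' with a rapid reset occupying 10% of the cycle), and an irregular mode in
#' which each cycle's period and amplitude are perturbed by a seeded uniform
#' factor `1 + irregularity * U(-1, 1)`.
#'
#' Displacement is peak-to-peak `amplitude` mm; phase 0 of the respiratory
#' cycle (end-inhale) corresponds to surrogate maxima.
#'
#' @param kind `"sinusoidal"`, `"sawtooth"` or `"irregular"`.
#' @param breathing_rate_bpm Breathing rate in breaths/min; the nominal
#'   period is `60 / breathing_rate_bpm` seconds.
#' @param amplitude Peak-to-peak displacement (mm).
#' @param duration Trace duration (s); must cover at least two cycles.
#' @param sample_rate Samples per second (default 100).
#' @param irregularity Fractional per-cycle perturbation of period and
#'   amplitude (irregular mode; default 0.2 there, ignored otherwise).
#' @param seed Integer seed for the irregular mode (deterministic traces).
#' @return An object of class `motion_waveform` with `sample_times`,
#'   `surrogate`, `displacement`, `breathing_period`, `amplitude`, `kind`,
#'   `seed`.
#' @examples
#' wf <- generate_waveform("sinusoidal", breathing_rate_bpm = 12,
#'                         amplitude = 30, duration = 15)
#' plot(wf)
#' @export
generate_waveform <- function(kind = c("sinusoidal", "sawtooth", "irregular"),
                              breathing_rate_bpm = 12, amplitude = 30,
                              duration = 15, sample_rate = 100,
                              irregularity = 0.2, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(breathing_rate_bpm > 0, amplitude >= 0, sample_rate > 0)
  bp <- 60 / breathing_rate_bpm
  if (duration < 2 * bp) {
    stop("insufficient cycles for phase sorting: duration must cover >= 2 ",
         "breathing periods (", signif(2 * bp, 4), " s)")
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  # unitless surrogate shape in [-1, 1]; the bellows signal exists (and
  # phase sorting works) even for a zero-excursion static acquisition
  if (kind == "sinusoidal") {
    s <- sin(2 * pi * t / bp)
  } else if (kind == "sawtooth") {
    # cycle starts at the end-inhale peak at t = bp/4 (first interior peak)
    phi <- ((t / bp) - 0.25) %% 1
    s <- ifelse(phi < 0.9, 1 - 2 * phi / 0.9, -1 + 2 * (phi - 0.9) / 0.1)
  } else {
    n_cycles <- ceiling(duration / bp * (1 + irregularity)) + 2L
    pars <- with_seed(seed, {
      u <- stats::runif(n_cycles, -1, 1)
      v <- stats::runif(n_cycles, -1, 1)
      list(periods = bp * (1 + irregularity * u),
           rel_amps = 1 + irregularity * v)
    })
    starts <- c(0, cumsum(pars$periods))
    cyc <- findInterval(t, starts, rightmost.closed = FALSE)
    cyc <- pmin(pmax(cyc, 1L), n_cycles)
    local_t <- t - starts[cyc]
    s <- pars$rel_amps[cyc] * sin(2 * pi * local_t / pars$periods[cyc])
  }
  d <- (amplitude / 2) * s
  structure(
    list(kind = kind, breathing_period = bp, amplitude = amplitude,
         sample_times = t, surrogate = s, displacement = d,
         irregularity = if (kind == "irregular") irregularity else 0,
         seed = as.integer(seed)),
    class = "motion_waveform"
  )
}

#' @export
print.motion_waveform <- function(x, ...) {
  cat(sprintf("%s waveform: period %.3g s (%.3g bpm), %g mm peak-to-peak, %g s\n",
              x$kind, x$breathing_period, 60 / x$breathing_period,
              x$amplitude, max(x$sample_times)))
  invisible(x)
}

#' @export
plot.motion_waveform <- function(x, ...) {
  plot(x$sample_times, x$displacement, type = "l",
       xlab = "time (s)", ylab = "displacement (mm)",
       main = sprintf("%s waveform", x$kind), ...)
  invisible(x)
}

#' Waveform displacement at arbitrary times
#'
#' Linear interpolation of the sampled displacement trace.
#'
#' @param waveform A [generate_waveform()] result.
#' @param t Times in seconds (within the trace support).
#' @return Displacement in mm.
#' @export
waveform_displacement <- function(waveform, t) {
  stopifnot(inherits(waveform, "motion_waveform"))
  rng <- range(waveform$sample_times)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9)) {
    stop("time outside waveform support")
  }
  stats::approx(waveform$sample_times, waveform$displacement, xout = t,
                rule = 2)$y
}

# per-object displacement vector (dx, dy) at scaled waveform displacement d
object_offset <- function(obj, d, amplitude) {
  if (obj$motion_axis == "none" || obj$excursion == 0) return(c(0, 0))
  scale <- if (amplitude > 0) obj$excursion / amplitude else 0
  if (obj$motion_axis == "AP") c(d * scale, 0) else c(0, d * scale)
}

# rasterize one object, displaced by (dx, dy), onto grid; returns list of
# index vector and coverage values (area-weighted anti-aliasing at edges)
rasterize_object <- function(obj, offset, grid) {
  cx <- obj$center[1] + offset[1]
  cy <- obj$center[2] + offset[2]
  h <- grid$spacing
  cc <- grid$coords
  n <- grid$n
  if (obj$shape == "disk") {
    r <- obj$size / 2
    xr <- which(abs(cc - cx) <= r + h)
    yr <- which(abs(cc - cy) <= r + h)
    if (length(xr) == 0L || length(yr) == 0L) {
      return(list(idx = integer(0), cov = numeric(0)))
    }
    dx <- cc[xr] - cx
    dy <- cc[yr] - cy
    dist <- sqrt(outer(dx^2, dy^2, "+"))
    cov <- matrix(0, length(dx), length(dy))
    cov[dist <= r - h] <- 1
    # boundary pixels: exact-area estimate by 8x8 subpixel sampling
    bnd <- which(dist > r - h & dist < r + h, arr.ind = TRUE)
    if (nrow(bnd) > 0) {
      ss <- (seq_len(8) - 4.5) / 8 * h
      sub <- expand.grid(sx = ss, sy = ss)
      for (b in seq_len(nrow(bnd))) {
        px <- dx[bnd[b, 1]]; py <- dy[bnd[b, 2]]
        cov[bnd[b, 1], bnd[b, 2]] <-
          mean((px + sub$sx)^2 + (py + sub$sy)^2 <= r^2)
      }
    }
  } else {
    wx <- obj$size[1] / 2
    wy <- obj$size[2] / 2
    xr <- which(abs(cc - cx) <= wx + h)
    yr <- which(abs(cc - cy) <= wy + h)
    if (length(xr) == 0L || length(yr) == 0L) {
      return(list(idx = integer(0), cov = numeric(0)))
    }
    # exact 1-D pixel overlap fractions for an axis-aligned rectangle
    fx <- clamp01((pmin(cc[xr] + h / 2, cx + wx) -
                   pmax(cc[xr] - h / 2, cx - wx)) / h)
    fy <- clamp01((pmin(cc[yr] + h / 2, cy + wy) -
                   pmax(cc[yr] - h / 2, cy - wy)) / h)
    cov <- outer(fx, fy)
  }
  idx <- outer(xr, (yr - 1L) * n, "+")
  keep <- cov > 0
  list(idx = idx[keep], cov = cov[keep])
}

#' Rasterize the phantom at a time point
#'
#' Renders the attenuation map of the phantom with each moving object
#' displaced along its motion axis by the waveform displacement at time `t`
#' (scaled to the object's excursion). Object edges are rendered with
#' area-weighted partial-volume anti-aliasing, so the integral of
#' attenuation over the grid is conserved as objects translate.
#'
#' @param phantom List of [phantom_object()]s.
#' @param waveform A [generate_waveform()] result (ignored if all objects
#'   are static; may be `NULL` then).
#' @param t Time in seconds within the waveform support.
#' @param grid An [image_grid()].
#' @param background Background attenuation (1/mm), default 0.
#' @return `n` x `n` attenuation matrix (`img[ix, iy]`).
#' @export
phantom_at_time <- function(phantom, waveform, t, grid, background = 0) {
  stopifnot(inherits(grid, "image_grid"))
  if (inherits(phantom, "phantom_object")) phantom <- list(phantom)
  moving <- any(vapply(phantom, function(o)
    o$motion_axis != "none" && o$excursion > 0, logical(1)))
  d <- if (moving) waveform_displacement(waveform, t) else 0
  amp <- if (moving) waveform$amplitude else 0
  img <- matrix(background, grid$n, grid$n)
  half_fov <- grid$fov / 2
  for (obj in phantom) {
    off <- object_offset(obj, d, amp)
    reach <- max(obj$size) / 2
    ctr <- obj$center + off
    if (any(abs(ctr) + reach > half_fov)) {
      warning("object displaced to the edge of the FOV; clipping")
    }
    ras <- rasterize_object(obj, off, grid)
    img[ras$idx] <- img[ras$idx] + ras$cov * obj$attenuation
  }
  img
}

#' Standard phantom suites mirroring the motion-platform protocol
#'
#' Factory for the factorial study conditions: objects embedded in a
#' lung-mimicking (near-air) slab, translated superior-inferior under a
#' sinusoidal waveform or anterior-posterior under a sawtooth waveform, over
#' grids of breathing rates and couch pitches, plus a matched static
#' ground-truth configuration (zero-amplitude waveform).
#'
#' * `si_sinusoid_grid`: two soft-tissue disks (54 mm and 36 mm) moving SI,
#'   30 mm peak-to-peak sinusoid; rates 10, 12, 15, 20 bpm x pitches 0.06,
#'   0.08, 0.10.
#' * `ap_sawtooth_grid`: one small high-contrast 8 mm disk moving AP, 30 mm
#'   peak-to-peak sawtooth; rates 8, 10, 12 bpm x pitches 0.06, 0.08, 0.10.
#' * `static_truth`: the SI phantom with a zero-amplitude waveform.
#'
#' @param name Suite name.
#' @return List with `name`, `phantom` (list of objects), `background`,
#'   `waveform_kind`, `amplitude` (mm peak-to-peak), and `configs`
#'   (data.frame of `bpm`, `pitch` rows).
#' @export
standard_phantom_suite <- function(name = c("si_sinusoid_grid",
                                            "ap_sawtooth_grid",
                                            "static_truth")) {
  name <- match.arg(name)
  slab <- phantom_object("rectangle", center = c(0, 0), size = c(360, 220),
                         attenuation = 0.0005, motion_axis = "none")
  si_objects <- list(
    slab,
    phantom_object("disk", center = c(-80, 0), size = 54,
                   attenuation = 0.019, motion_axis = "SI", excursion = 30),
    phantom_object("disk", center = c(80, 0), size = 36,
                   attenuation = 0.019, motion_axis = "SI", excursion = 30)
  )
  ap_objects <- list(
    slab,
    phantom_object("disk", center = c(0, 40), size = 8,
                   attenuation = 0.025, motion_axis = "AP", excursion = 30)
  )
  switch(name,
    si_sinusoid_grid = list(
      name = name, phantom = si_objects, background = 0,
      waveform_kind = "sinusoidal", amplitude = 30,
      configs = expand.grid(bpm = c(10, 12, 15, 20),
                            pitch = c(0.06, 0.08, 0.10))
    ),
    ap_sawtooth_grid = list(
      name = name, phantom = ap_objects, background = 0,
      waveform_kind = "sawtooth", amplitude = 30,
      configs = expand.grid(bpm = c(8, 10, 12),
                            pitch = c(0.06, 0.08, 0.10))
    ),
    static_truth = list(
      name = name, phantom = si_objects, background = 0,
      waveform_kind = "sinusoidal", amplitude = 0,
      configs = data.frame(bpm = 12, pitch = 0.10)
    )
  )
}
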