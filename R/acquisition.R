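#' Acquire a time-stamped dynamic sinogram of the moving phantom
#'
#' Simulates continuous-rotation parallel-beam acquisition: projection `k`
#' is taken at time `t_k = (k-1) * RT / PPR` and gantry angle
#' `theta_k = 2*pi*(k-1)/PPR mod 2*pi`, and holds the line integrals of the
#' phantom frozen at `t_k`. Optional zero-mean Gaussian noise of standard
#' deviation `noise_sigma` (attenuation-length units) is added to the line
#' integrals, seeded for reproducibility.
#'
#' The couch is not geometrically simulated: pitch enters the system only
#' through the gating temporal budget ([gating_budget()]). Because every
#' object translates rigidly, the default forward model computes one static
#' sinogram per motion group and assembles each time point by the
#' parallel-beam shift theorem (a rigid in-plane translation `d` shifts the
#' projection along the detector by `d . (cos theta, sin theta)`), which is
#' exact for the continuous phantom up to the linear detector interpolation.
#' `method = "direct"` instead rasterizes and projects the phantom at every
#' time point (slow; used for cross-checking).
#'
#' @param phantom List of [phantom_object()]s.
#' @param waveform A [generate_waveform()] result covering `duration`.
#' @param geom A [scanner_geometry()].
#' @param duration Acquisition duration in seconds (at least two breathing
#'   periods).
#' @param grid An [image_grid()]; its FOV should match the geometry's.
#' @param noise_sigma Gaussian noise sd on line integrals (default 0).
#' @param seed Integer seed for the noise stream.
#' @param background Background attenuation passed to the rasterizer.
#' @param method `"shift"` (default) or `"direct"`.
#' @return An object of class `dynamic_sinogram`: list with `data`
#'   (`n_det` x `n_proj` matrix), `angles`, `times`, `geometry`, `waveform`,
#'   `grid`, `noise_sigma`, `seed`.
#' @export
acquire <- function(phantom, waveform, geom, duration, grid,
                    noise_sigma = 0, seed = 1L, background = 0,
                    method = c("shift", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(waveform, "motion_waveform"),
            inherits(geom, "scanner_geometry"),
            inherits(grid, "image_grid"))
  if (inherits(phantom, "phantom_object")) phantom <- list(phantom)
  bp <- waveform$breathing_period
  if (duration < 2 * bp) {
    stop("acquisition must cover at least two breathing periods")
  }
  if (duration > max(waveform$sample_times) + 1e-9) {
    stop("waveform trace shorter than the acquisition duration")
  }
  ppr <- geom$projections_per_rotation
  rt <- geom$rotation_time
  dt <- rt / ppr
  n_proj <- floor(duration / dt) + 1L
  times <- (seq_len(n_proj) - 1L) * dt
  aidx <- ((seq_len(n_proj) - 1L) %% ppr) + 1L
  base_angles <- 2 * pi * (seq_len(ppr) - 1L) / ppr
  angles <- base_angles[aidx]
  n_det <- grid$n

  if (method == "direct") {
    data <- matrix(0, n_det, n_proj)
    for (k in seq_len(n_proj)) {
      img <- phantom_at_time(phantom, waveform, times[k], grid, background)
      data[, k] <- project_image(img, grid, angles[k])
    }
  } else {
    # group objects sharing a rigid motion (axis, excursion); "none" = static
    keys <- vapply(phantom, function(o) {
      if (o$motion_axis == "none" || o$excursion == 0) "static"
      else paste(o$motion_axis, o$excursion)
    }, character(1))
    disp <- waveform_displacement(waveform, times)
    amp <- waveform$amplitude
    data <- matrix(0, n_det, n_proj)
    for (key in unique(keys)) {
      objs <- phantom[keys == key]
      bg <- if (key == "static") background else 0
      img <- matrix(bg, grid$n, grid$n)
      for (obj in objs) {
        ras <- rasterize_object(obj, c(0, 0), grid)
        img[ras$idx] <- img[ras$idx] + ras$cov * obj$attenuation
      }
      sgram <- project_image(img, grid, base_angles)
      if (key == "static") {
        data <- data + sgram[, aidx]
      } else {
        o1 <- objs[[1]]
        scale <- if (amp > 0) o1$excursion / amp else 0
        comp <- if (o1$motion_axis == "AP") cos(angles) else sin(angles)
        shift_px <- disp * scale * comp / grid$spacing
        # p_moving(u) = p_static(u - s): sample each static profile at j - s
        g <- outer(seq_len(n_det), shift_px, "-")
        i0 <- floor(g)
        fr <- g - i0
        colbase <- rep((aidx - 1L) * n_det, each = n_det)
        pick <- function(ii) {
          ok <- ii >= 1 & ii <= n_det
          v <- numeric(length(ii))
          v[ok] <- sgram[ii[ok] + colbase[ok]]
          v
        }
        data <- data + matrix(pick(i0) * (1 - fr) + pick(i0 + 1L) * fr,
                              n_det, n_proj)
      }
    }
  }
  if (noise_sigma > 0) {
    data <- data + with_seed(seed, matrix(
      stats::rnorm(length(data), 0, noise_sigma), n_det, n_proj))
  }
  structure(
    list(data = data, angles = angles, angle_index = aidx, times = times,
         geometry = geom, waveform = waveform, grid = grid,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         background = background),
    class = "dynamic_sinogram"
  )
}

#' @export
print.dynamic_sinogram <- function(x, ...) {
  cat(sprintf("Dynamic sinogram: %d projections x %d detectors, %.3g s\n",
              ncol(x$data), nrow(x$data), max(x$times)))
  cat(sprintf("  %s waveform, period %.3g s; noise sigma %g\n",
              x$waveform$kind, x$waveform$breathing_period, x$noise_sigma))
  if (!is.null(x$phase_fraction)) {
    cat(sprintf("  phase-tagged into %d bins\n", x$n_phases))
  }
  invisible(x)
}

#' Detect respiratory peaks in a surrogate trace
#'
#' Finds local maxima of the sampled surrogate that rise above
#' `mean + prominence * (max - mean)`, then refines each peak time by
#' fitting a parabola through the three samples around the maximum
#' (quadratic sub-sample interpolation). Deterministic.
#'
#' @param surrogate Sampled surrogate signal.
#' @param times Sample times (s), same length.
#' @param prominence Fractional height threshold above the mean
#'   (default 0.25).
#' @return Vector of refined peak times (possibly empty).
#' @export
peak_detect <- function(surrogate, times, prominence = 0.25) {
  stopifnot(length(surrogate) == length(times), length(surrogate) >= 3)
  rng <- max(surrogate) - mean(surrogate)
  if (rng <= 0) return(numeric(0))
  thr <- mean(surrogate) + prominence * rng
  pk <- pracma::findpeaks(surrogate, minpeakheight = thr, zero = "+")
  if (is.null(pk)) return(numeric(0))
  idx <- sort(pk[, 2])
  dt <- times[2] - times[1]
  refined <- vapply(idx, function(i) {
    if (i <= 1L || i >= length(surrogate)) return(times[i])
    y0 <- surrogate[i - 1L]; y1 <- surrogate[i]; y2 <- surrogate[i + 1L]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(times[i])
    delta <- 0.5 * (y0 - y2) / den
    times[i] + max(-0.5, min(0.5, delta)) * dt
  }, numeric(1))
  refined
}

#' Tag projections with retrospective respiratory phase
#'
#' Detects end-inhale peaks on the waveform surrogate and assigns each
#' projection the elapsed fraction of its local peak-to-peak interval
#' (`phase_fraction` in `[0, 1)`, 0 = end-inhale). Before the first and
#' after the last detected peak, the adjacent interval length is used to
#' extrapolate. Phase bins are centered on the bin fractions:
#' `bin = round(phase_fraction * n_phases) mod n_phases`, so bin 0 is
#' centered on end-inhale and bin `n_phases/2` on end-exhale for symmetric
#' waveforms.
#'
#' @param sino A [acquire()]d `dynamic_sinogram`.
#' @param n_phases Number of phase bins (default 10).
#' @return The sinogram with `phase_fraction`, `phase_bin`, `cycle_index`
#'   and `n_phases` fields added.
#' @export
assign_phases <- function(sino, n_phases = 10L) {
  stopifnot(inherits(sino, "dynamic_sinogram"), n_phases >= 1)
  wf <- sino$waveform
  peaks <- peak_detect(wf$surrogate, wf$sample_times)
  if (length(peaks) < 2L) {
    stop("cannot phase-sort: fewer than two surrogate peaks detected")
  }
  # extrapolate one-interval copies so every projection has bracketing peaks
  first_int <- peaks[2] - peaks[1]
  last_int <- peaks[length(peaks)] - peaks[length(peaks) - 1L]
  tmin <- min(sino$times); tmax <- max(sino$times)
  while (peaks[1] > tmin) peaks <- c(peaks[1] - first_int, peaks)
  while (peaks[length(peaks)] <= tmax) {
    peaks <- c(peaks, peaks[length(peaks)] + last_int)
  }
  iv <- findInterval(sino$times, peaks, rightmost.closed = FALSE)
  iv <- pmin(pmax(iv, 1L), length(peaks) - 1L)
  frac <- (sino$times - peaks[iv]) / (peaks[iv + 1L] - peaks[iv])
  frac <- frac %% 1
  sino$phase_fraction <- frac
  sino$cycle_index <- iv
  sino$phase_bin <- as.integer(round(frac * n_phases)) %% as.integer(n_phases)
  sino$n_phases <- as.integer(n_phases)
  sino
}

#' Export per-projection metadata as CSV
#'
#' Writes one row per projection: index, angle, timestamp and (if the
#' sinogram is phase-tagged) phase fraction, phase bin and cycle index.
#'
#' @param sino A `dynamic_sinogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_projection_metadata <- function(sino, path) {
  stopifnot(inherits(sino, "dynamic_sinogram"))
  df <- data.frame(index = seq_along(sino$times), angle = sino$angles,
                   time = sino$times)
  if (!is.null(sino$phase_fraction)) {
    df$phase_fraction <- sino$phase_fraction
    df$phase_bin <- sino$phase_bin
    df$cycle_index <- sino$cycle_index
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
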