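# Weighted filtered backprojection over temporal gating windows.

# Band-limited ramp (Ram-Lak) filter kernel, arranged for circular
# convolution of length L (Kak & Slaney discrete form):
# h(0) = 1/(4 du^2), h(k odd) = -1/(pi^2 k^2 du^2), h(k even) = 0.
ramp_kernel_fft <- function(n_det, det_spacing, apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  L <- 2^ceiling(log2(2 * n_det))
  k <- c(0:(L / 2), -(L / 2 - 1):-1)
  h <- numeric(L)
  h[k == 0] <- 1 / (4 * det_spacing^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2 * det_spacing^2)
  H <- Re(stats::fft(h))
  if (apodization == "hann") {
    f <- c(0:(L / 2), (L / 2 - 1):1) / (L / 2)
    H <- H * (0.5 + 0.5 * cos(pi * f))
  }
  list(H = H, L = L)
}

# Ramp-filter every column of a sinogram matrix (n_det x n_proj).
filter_sinogram_matrix <- function(data, det_spacing,
                                   apodization = c("none", "hann")) {
  n_det <- nrow(data)
  rk <- ramp_kernel_fft(n_det, det_spacing, apodization)
  pad <- matrix(0, rk$L, ncol(data))
  pad[seq_len(n_det), ] <- data
  ft <- stats::mvfft(pad)
  filt <- Re(stats::mvfft(ft * rk$H, inverse = TRUE)) / rk$L
  filt[seq_len(n_det), , drop = FALSE] * det_spacing
}

#' Ramp-filter a dynamic sinogram once
#'
#' Precomputes the ramp-filtered projections and caches them on the
#' sinogram so repeated phase reconstructions do not refilter.
#'
#' @param sino A `dynamic_sinogram`.
#' @param apodization `"none"` (default) or `"hann"`.
#' @return The sinogram with a `filtered` matrix added.
#' @export
filter_sinogram <- function(sino, apodization = c("none", "hann")) {
  stopifnot(inherits(sino, "dynamic_sinogram"))
  sino$filtered <- filter_sinogram_matrix(sino$data, sino$grid$spacing,
                                          apodization)
  sino
}

# Backproject per-angle combined filtered profiles Q (n_det x n_angles)
# at 'angles' onto the grid; returns n x n image (no angular scaling).
backproject_profiles <- function(Q, angles, grid) {
  n <- grid$n
  n_det <- nrow(Q)
  cc <- grid$coords
  h <- grid$spacing
  img <- matrix(0, n, n)
  off <- (n_det + 1) / 2
  for (a in seq_along(angles)) {
    th <- angles[a]
    g <- outer(cc * cos(th), cc * sin(th), "+") / h + off
    i0 <- floor(g)
    fr <- g - i0
    col <- Q[, a]
    ok0 <- i0 >= 1 & i0 <= n_det
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= n_det
    v <- matrix(0, n, n)
    if (any(ok0)) v[ok0] <- col[i0[ok0]] * (1 - fr[ok0])
    if (any(ok1)) v[ok1] <- v[ok1] + col[i0[ok1] + 1] * fr[ok1]
    img <- img + v
  }
  img
}

#' Select the temporal gating window for a phase bin
#'
#' Chooses the phase point: the projection whose phase tag is nearest (in
#' circular distance) to the bin center `phase_bin / n_phases`, restricted
#' to positions where the full window fits inside the acquisition; ties go
#' to the earliest projection. The window is the contiguous run of
#' `budget$window_projection_count` projections centered there.
#'
#' @param sino A phase-tagged `dynamic_sinogram` ([assign_phases()]).
#' @param phase_bin Phase bin in `0 .. n_phases-1`.
#' @param budget A [gating_budget()] for this geometry and breathing period.
#' @return List with `indices` (projection indices of the window),
#'   `center_index` (global index of the phase point), `mid_phase_local`
#'   (its position within the window).
#' @export
select_window <- function(sino, phase_bin, budget) {
  stopifnot(inherits(sino, "dynamic_sinogram"),
            !is.null(sino$phase_fraction),
            inherits(budget, "gating_budget"))
  n_phases <- sino$n_phases
  stopifnot(phase_bin >= 0, phase_bin < n_phases)
  it <- budget$window_projection_count
  n_proj <- ncol(sino$data)
  lo <- floor(it / 2)
  hi <- it - 1L - lo
  fit <- seq_len(n_proj) >= (1L + lo) & seq_len(n_proj) <= (n_proj - hi)
  if (!any(fit)) {
    stop("insufficient acquisition duration: gating window (", it,
         " projections) does not fit")
  }
  center_frac <- phase_bin / n_phases
  d <- abs(sino$phase_fraction - center_frac)
  d <- pmin(d, 1 - d)
  d[!fit] <- Inf
  c_idx <- which.min(d)  # which.min returns the earliest among exact ties
  list(indices = (c_idx - lo):(c_idx + hi),
       center_index = c_idx,
       mid_phase_local = lo + 1L)
}

# core weighted FBP over an explicit window
reconstruct_window <- function(sino, window, scheme, steepness = 2,
                               apodization = "none") {
  geom <- sino$geometry
  ppr <- geom$projections_per_rotation
  idx <- window$indices
  it <- length(idx)
  curve <- build_weight_curve(it, scheme, steepness = steepness)
  # conjugate-ray redundancy groups: same angle modulo half a rotation
  half <- as.integer(ceiling(ppr / 2))
  ray_group <- (sino$angle_index[idx] - 1L) %% half
  curve <- normalize_weights(curve, ray_group)
  filt <- if (!is.null(sino$filtered)) sino$filtered[, idx, drop = FALSE]
          else filter_sinogram_matrix(sino$data[, idx, drop = FALSE],
                                      sino$grid$spacing, apodization)
  # combine rows sharing an identical gantry angle before backprojection
  agrp <- sino$angle_index[idx]
  Qt <- rowsum(t(filt) * curve$normalized, group = agrp)
  ang_ids <- as.integer(rownames(Qt))
  angles <- 2 * pi * (ang_ids - 1L) / ppr
  img <- backproject_profiles(t(Qt), angles, sino$grid)
  img * (2 * pi / ppr)
}

#' Reconstruct one respiratory phase by weighted FBP
#'
#' Ramp-filtered parallel-beam backprojection over the phase's temporal
#' gating window, with per-projection temporal weights (cosine-squared,
#' EXPO, or uniform) normalized within conjugate-ray redundancy groups.
#' When the gating window is at its half-rotation minimum (no widening),
#' every ray is measured once, weighting cannot redistribute anything, and
#' the scheme is forced to `uniform` — the regime in which no weighting
#' scheme is employed.
#'
#' @param sino A phase-tagged `dynamic_sinogram`.
#' @param phase_bin Phase bin in `0 .. n_phases-1`.
#' @param scheme `"cosine_squared"`, `"expo"` or `"uniform"`.
#' @param budget Optional [gating_budget()]; computed from the geometry and
#'   the waveform's breathing period if missing.
#' @param steepness EXPO steepness (default 2).
#' @param apodization Filter apodization (default none).
#' @return An object of class `phase_image`: list with `pixels` (n x n
#'   attenuation matrix), `phase_bin`, `scheme`, `window_indices`,
#'   `weight_curve`, `grid`.
#' @export
reconstruct_phase <- function(sino, phase_bin,
                              scheme = c("cosine_squared", "expo", "uniform"),
                              budget = NULL, steepness = 2,
                              apodization = "none") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(sino, "dynamic_sinogram"))
  if (is.null(sino$phase_fraction)) stop("sinogram is not phase-tagged")
  if (is.null(budget)) {
    budget <- gating_budget(sino$geometry, sino$waveform$breathing_period)
  }
  window <- select_window(sino, phase_bin, budget)
  scheme_used <- if (budget$window_widening <= 0) "uniform" else scheme
  img <- reconstruct_window(sino, window, scheme_used, steepness, apodization)
  structure(
    list(pixels = img, phase_bin = as.integer(phase_bin),
         scheme = scheme, scheme_used = scheme_used,
         window_indices = window$indices,
         weight_curve = build_weight_curve(length(window$indices),
                                           scheme_used, steepness = steepness),
         grid = sino$grid),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("Phase image: bin %d, %s weighting (%s applied), %d-projection window\n",
              x$phase_bin, x$scheme, x$scheme_used, length(x$window_indices)))
  cat(sprintf("  %d x %d px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Reconstruct all phases of a 4DCT
#'
#' Maps [reconstruct_phase()] over all phase bins, filtering the sinogram
#' once. Deterministic.
#'
#' @inheritParams reconstruct_phase
#' @param n_phases Number of phase bins (default 10); the sinogram is
#'   (re)tagged if needed.
#' @return List of `n_phases` [reconstruct_phase()] images (bins
#'   `0 .. n_phases-1`).
#' @export
reconstruct_4dct <- function(sino, n_phases = 10L,
                             scheme = c("cosine_squared", "expo", "uniform"),
                             budget = NULL, steepness = 2,
                             apodization = "none") {
  scheme <- match.arg(scheme)
  if (is.null(sino$phase_fraction) || !identical(sino$n_phases,
                                                 as.integer(n_phases))) {
    sino <- assign_phases(sino, n_phases)
  }
  if (is.null(sino$filtered)) sino <- filter_sinogram(sino, apodization)
  if (is.null(budget)) {
    budget <- gating_budget(sino$geometry, sino$waveform$breathing_period)
  }
  lapply(0:(as.integer(n_phases) - 1L), function(b) {
    reconstruct_phase(sino, b, scheme, budget, steepness, apodization)
  })
}

#' Reconstruct a static (motion-free) reference image
#'
#' Standard unweighted FBP over the first full rotation of projections;
#' used as the ground-truth reference for residual-blur measurements.
#'
#' @param sino A `dynamic_sinogram` of a static phantom covering at least
#'   one rotation.
#' @param apodization Filter apodization (default none).
#' @return A `phase_image` with `phase_bin = NA`.
#' @export
reconstruct_static <- function(sino, apodization = "none") {
  stopifnot(inherits(sino, "dynamic_sinogram"))
  ppr <- sino$geometry$projections_per_rotation
  if (ncol(sino$data) < ppr) stop("need at least one full rotation")
  window <- list(indices = seq_len(ppr), center_index = ppr %/% 2L,
                 mid_phase_local = ppr %/% 2L)
  img <- reconstruct_window(sino, window, "uniform",
                            apodization = apodization)
  structure(
    list(pixels = img, phase_bin = NA_integer_, scheme = "uniform",
         scheme_used = "uniform", window_indices = window$indices,
         weight_curve = build_weight_curve(ppr, "uniform"),
         grid = sino$grid),
    class = "phase_image"
  )
}

#' Derivative images over the phase stack
#'
#' Voxelwise maximum (MIP), minimum (minIP) and mean (average CT) across
#' the reconstructed phases.
#'
#' @param phases List of `phase_image`s on congruent grids.
#' @return List of class `derivative_images` with matrices `mip`, `minip`,
#'   `avg`.
#' @export
derivative_images <- function(phases) {
  stopifnot(length(phases) >= 1)
  mats <- lapply(phases, function(p) {
    if (inherits(p, "phase_image")) p$pixels else p
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) stop("phase images have mismatched grids")
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  structure(
    list(mip = apply(arr, c(1, 2), max),
         minip = apply(arr, c(1, 2), min),
         avg = apply(arr, c(1, 2), mean)),
    class = "derivative_images"
  )
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param image Attenuation matrix or `phase_image`.
#' @param mu_water Linear attenuation of water (1/mm); default 0.019.
#' @return Matrix in HU.
#' @export
to_hu <- function(image, mu_water = 0.019) {
  stopifnot(mu_water > 0)
  if (inherits(image, "phase_image")) image <- image$pixels
  1000 * (image - mu_water) / mu_water
}
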