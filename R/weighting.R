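#' Cosine-squared temporal gating weight
#'
#' Conventional taper applied across the temporal gating window so that
#' projections temporally distant from the reconstruction phase point
#' contribute less: `w(i) = cos^2(pi * (i - mid_phase) / total)`. The weight
#' is 1 at the phase point, falls to 0 at the window edges
#' (`|i - mid_phase| = total/2`), and is 0 for indices outside the window
#' (such projections are simply not used).
#'
#' @param i Projection index (vectorized).
#' @param mid_phase Index of the mid-phase (reconstruction phase point).
#' @param total Total number of projections in the window.
#' @return Weight(s) in `[0, 1]`.
#' @export
cosine_squared_weight <- function(i, mid_phase, total) {
  stopifnot(total >= 1)
  off <- i - mid_phase
  w <- cos(pi * off / total)^2
  w[abs(off) > total / 2] <- 0
  w
}

#' Exponential sharpening term
#'
#' Decaying exponential `exp(-|i - center| * steepness / total)` multiplied
#' into the cosine-squared taper to further suppress temporally distant
#' projections. Larger `steepness` gives a steeper fall-off; `steepness = 0`
#' degenerates to 1 everywhere (pure cosine-squared weighting). The clinical
#' default steepness is 2.
#'
#' @param i Projection index (vectorized).
#' @param center Index at which the exponential peaks (normally the
#'   mid-phase point).
#' @param total Total number of projections in the window.
#' @param steepness Non-negative fall-off control.
#' @return Value(s) in `(0, 1]`.
#' @export
exponential_term <- function(i, center, total, steepness) {
  stopifnot(total >= 1, steepness >= 0)
  exp(-abs(i - center) * steepness / total)
}

#' EXPO temporal gating weight
#'
#' The exponential-sharpened gating weight: the product of
#' [cosine_squared_weight()] and [exponential_term()]. For non-negative
#' steepness it is pointwise bounded above by the cosine-squared weight, with
#' equality only at the phase point (or steepness 0), which is what sharpens
#' the effective temporal window.
#'
#' @inheritParams cosine_squared_weight
#' @param exp_center Index at which the exponential factor peaks; defaults
#'   to the mid-phase point.
#' @param steepness Non-negative fall-off control (clinical default 2).
#' @return Weight(s) in `[0, 1]`.
#' @export
expo_weight <- function(i, mid_phase, total, exp_center = mid_phase,
                        steepness = 2) {
  cosine_squared_weight(i, mid_phase, total) *
    exponential_term(i, exp_center, total, steepness)
}

#' Build a temporal weight curve over a gating window
#'
#' Evaluates one of the gating weighting schemes over a window of `total`
#' consecutive projections, with the mid-phase point at the central index
#' (`floor(total/2) + 1`). The `uniform` scheme is the no-weighting case used
#' when the gating window is constrained to its half-rotation minimum.
#'
#' @param total Number of projections in the window.
#' @param scheme One of `"cosine_squared"`, `"expo"`, `"uniform"`.
#' @param steepness Exponential steepness (used by `"expo"`; default 2).
#' @param exp_center Index of the exponential peak; defaults to the
#'   mid-phase index.
#' @return An object of class `weight_curve`: list with `weights` (length
#'   `total`, raw, in `[0,1]`), `total_projections`, `mid_phase_index`,
#'   `exp_center_index`, `steepness`, `scheme`.
#' @examples
#' wc <- build_weight_curve(64, "expo")
#' plot(wc)
#' @export
build_weight_curve <- function(total,
                               scheme = c("cosine_squared", "expo", "uniform"),
                               steepness = 2, exp_center = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(total >= 1)
  total <- as.integer(total)
  im <- floor(total / 2) + 1L
  ih <- if (is.null(exp_center)) im else as.integer(exp_center)
  idx <- seq_len(total)
  w <- switch(scheme,
    uniform = rep(1, total),
    cosine_squared = cosine_squared_weight(idx, im, total),
    expo = expo_weight(idx, im, total, exp_center = ih, steepness = steepness)
  )
  structure(
    list(
      weights = w,
      total_projections = total,
      mid_phase_index = im,
      exp_center_index = ih,
      steepness = if (scheme == "expo") steepness else 0,
      scheme = scheme
    ),
    class = "weight_curve"
  )
}

#' @export
print.weight_curve <- function(x, ...) {
  cat(sprintf("Temporal weight curve: %s, %d projections, mid-phase at %d\n",
              x$scheme, x$total_projections, x$mid_phase_index))
  if (x$scheme == "expo") {
    cat(sprintf("  steepness %.3g, exponential centered at %d\n",
                x$steepness, x$exp_center_index))
  }
  cat(sprintf("  FWHM of curve: %.2f projections\n",
              effective_temporal_width(x)))
  invisible(x)
}

#' @export
plot.weight_curve <- function(x, ...) {
  plot(seq_len(x$total_projections), x$weights, type = "l",
       xlab = "projection index", ylab = "raw weight",
       main = sprintf("%s weight curve", x$scheme), ...)
  graphics::abline(v = x$mid_phase_index, lty = 3)
  invisible(x)
}

#' Normalize weights within redundancy groups
#'
#' Projections acquired half a rotation apart measure the same parallel-beam
#' ray (up to a detector flip); within each such redundancy group the raw
#' temporal weights are rescaled to sum to one so that every ray contributes
#' with unit total weight to the reconstruction, preserving the relative
#' temporal ordering.
#'
#' @param curve A [build_weight_curve()] result (or any `weight_curve`).
#' @param redundancy_groups Integer/factor vector of length
#'   `total_projections` labelling, for each window index, its ray
#'   redundancy group.
#' @return The curve with an added `normalized` weight vector.
#' @export
normalize_weights <- function(curve, redundancy_groups) {
  stopifnot(inherits(curve, "weight_curve"),
            length(redundancy_groups) == curve$total_projections)
  g <- as.integer(factor(redundancy_groups))
  sums <- tapply(curve$weights, g, sum)
  if (any(sums <= 0)) {
    stop("insufficient data for ray: a redundancy group has zero total weight")
  }
  curve$normalized <- curve$weights / as.numeric(sums[g])
  curve
}

#' Effective temporal width of a weight curve
#'
#' Full width at half maximum of the raw weight curve, with the half-maximum
#' crossings located by linear interpolation between indices. For a uniform
#' curve this is the window length; for a cosine-squared window of length
#' `It` it is `It/2`; the exponential factor shrinks it further — this is the
#' quantitative sense in which the EXPO scheme sharpens the temporal window.
#'
#' @param curve A `weight_curve`.
#' @return Width in projections.
#' @export
effective_temporal_width <- function(curve) {
  stopifnot(inherits(curve, "weight_curve"))
  w <- curve$weights
  n <- length(w)
  if (n == 1L) return(1)
  peak <- max(w)
  if (peak <= 0) stop("degenerate weight curve: all weights zero")
  half <- peak / 2
  ipk <- which.max(w)
  below <- which(w < half)
  kl <- below[below < ipk]
  kr <- below[below > ipk]
  if (length(kl) == 0L && length(kr) == 0L) return(n)  # never crosses: full window
  left <- if (length(kl) == 0L) 1 else {
    k <- max(kl)
    k + (half - w[k]) / (w[k + 1L] - w[k])
  }
  right <- if (length(kr) == 0L) n else {
    k <- min(kr)
    (k - 1L) + (w[k - 1L] - half) / (w[k - 1L] - w[k])
  }
  right - left
}

#' Export a weight curve as CSV
#'
#' Writes one row per window index with the raw and (if present) normalized
#' weight, for plotting outside R.
#'
#' @param curve A `weight_curve`, optionally normalized.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_weight_curve <- function(curve, path) {
  stopifnot(inherits(curve, "weight_curve"))
  df <- data.frame(
    index = seq_len(curve$total_projections),
    raw_weight = curve$weights
  )
  if (!is.null(curve$normalized)) df$normalized_weight <- curve$normalized
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
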