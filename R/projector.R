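# Parallel-beam forward projection (ray-driven, bilinear sampling).

# Detector coordinates (mm): n_det bins of width det_spacing centered on the
# isocenter, same convention as image_grid pixel centers.
detector_coords <- function(n_det, det_spacing) {
  (seq_len(n_det) - (n_det + 1) / 2) * det_spacing
}

#' Parallel-beam forward projection of an image
#'
#' Computes line integrals of a pixel image along parallel rays. The ray at
#' angle `theta` and detector coordinate `u` is the line
#' `p(t) = u * (cos theta, sin theta) + t * (-sin theta, cos theta)`;
#' the integral is approximated by sampling the image with bilinear
#' interpolation at uniform steps along the ray (points outside the grid
#' read as zero) and summing times the step length.
#'
#' @param img `n` x `n` attenuation matrix (`img[ix, iy]`).
#' @param grid The [image_grid()] the image lives on.
#' @param angles Projection angles in radians (vector).
#' @param n_det Number of detector bins (default: grid size).
#' @param det_spacing Detector bin width in mm (default: pixel size).
#' @param step Ray sampling step in mm (default: half the pixel size).
#' @return `n_det` x `length(angles)` sinogram matrix.
#' @export
project_image <- function(img, grid, angles, n_det = grid$n,
                          det_spacing = grid$spacing,
                          step = grid$spacing / 2) {
  stopifnot(inherits(grid, "image_grid"), nrow(img) == grid$n,
            ncol(img) == grid$n)
  u <- detector_coords(n_det, det_spacing)
  half_diag <- grid$fov * 0.75
  tt <- seq(-half_diag, half_diag, by = step)
  out <- matrix(0, n_det, length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a]
    cs <- cos(th); sn <- sin(th)
    x <- outer(u * cs, -tt * sn, "+")
    y <- outer(u * sn, tt * cs, "+")
    vals <- bilinear_lookup(img, grid, as.vector(x), as.vector(y))
    out[, a] <- rowSums(matrix(vals, n_det)) * step
  }
  out
}
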