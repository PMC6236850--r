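#' Square image grid specification
#'
#' Pixel grid used for phantom rasterization and reconstruction: `n` x `n`
#' pixels spanning a square of side `fov` mm centered on the isocenter.
#' Pixel `(ix, iy)` has center `x = (ix - (n+1)/2) * spacing`,
#' `y = (iy - (n+1)/2) * spacing`, with x pointing anterior-posterior and y
#' superior-inferior in the axial slice convention used throughout.
#'
#' @param n Pixels per side.
#' @param fov Field of view side length (mm).
#' @return An object of class `image_grid` with `n`, `fov`, `spacing` and
#'   precomputed center coordinates `coords`.
#' @export
image_grid <- function(n = 256, fov = 500) {
  stopifnot(n >= 8, fov > 0)
  n <- as.integer(n)
  spacing <- fov / n
  structure(
    list(n = n, fov = fov, spacing = spacing,
         coords = (seq_len(n) - (n + 1) / 2) * spacing),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Image grid: %d x %d px, %g mm FOV, %.3f mm/px\n",
              x$n, x$n, x$fov, x$spacing))
  invisible(x)
}

# Bilinear interpolation of matrix img (img[ix, iy], grid-centered coords)
# at arbitrary points (x, y) in mm; points outside the grid read as zero.
bilinear_lookup <- function(img, grid, x, y) {
  n <- grid$n
  h <- grid$spacing
  gx <- x / h + (n + 1) / 2
  gy <- y / h + (n + 1) / 2
  ix0 <- floor(gx)
  iy0 <- floor(gy)
  fx <- gx - ix0
  fy <- gy - iy0
  out <- numeric(length(x))
  # each of the four neighbours contributes where it exists
  acc <- function(ii, jj, wt) {
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & wt > 0
    if (any(ok)) {
      idx <- ii[ok] + (jj[ok] - 1) * n
      out[ok] <<- out[ok] + wt[ok] * img[idx]
    }
  }
  acc(ix0,      iy0,      (1 - fx) * (1 - fy))
  acc(ix0 + 1L, iy0,      fx       * (1 - fy))
  acc(ix0,      iy0 + 1L, (1 - fx) * fy)
  acc(ix0 + 1L, iy0 + 1L, fx       * fy)
  out
}
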