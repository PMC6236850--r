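# Independent brute-force oracles for the forward projector and FBP.
# Deliberately written as plain loops, sharing only the sampling
# conventions (detector binning, ray step, bilinear reads, zero outside).

# Brute-force parallel-beam ray sums of an image: explicit loop over
# detector bins and ray sample points with scalar bilinear interpolation.
oracle_project <- function(img, grid, angles, step = grid$spacing / 2) {
  n <- grid$n
  h <- grid$spacing
  u <- (seq_len(n) - (n + 1) / 2) * h
  tt <- seq(-grid$fov * 0.75, grid$fov * 0.75, by = step)
  interp_one <- function(x, y) {
    gx <- x / h + (n + 1) / 2
    gy <- y / h + (n + 1) / 2
    ix <- floor(gx); iy <- floor(gy)
    fx <- gx - ix; fy <- gy - iy
    val <- 0
    for (dd in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      ii <- ix + dd[1]; jj <- iy + dd[2]
      w <- (if (dd[1] == 0) 1 - fx else fx) * (if (dd[2] == 0) 1 - fy else fy)
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && w > 0) {
        val <- val + w * img[ii, jj]
      }
    }
    val
  }
  out <- matrix(0, n, length(angles))
  for (a in seq_along(angles)) {
    cs <- cos(angles[a]); sn <- sin(angles[a])
    for (d in seq_len(n)) {
      s <- 0
      for (t in tt) {
        s <- s + interp_one(u[d] * cs - t * sn, u[d] * sn + t * cs)
      }
      out[d, a] <- s * step
    }
  }
  out
}

# Textbook filtered backprojection of a static sinogram over one half
# rotation: direct-space Ram-Lak convolution, then per-pixel backprojection
# with linear detector interpolation.
oracle_fbp <- function(sinogram, angles, grid) {
  n_det <- nrow(sinogram)
  h <- grid$spacing
  ks <- -(n_det - 1):(n_det - 1)
  kern <- numeric(length(ks))
  kern[ks == 0] <- 1 / (4 * h^2)
  odd <- ks %% 2 != 0
  kern[odd] <- -1 / (pi^2 * ks[odd]^2 * h^2)
  filt <- matrix(0, n_det, length(angles))
  for (a in seq_along(angles)) {
    full <- stats::convolve(sinogram[, a], rev(kern), type = "open")
    filt[, a] <- full[n_det:(2 * n_det - 1)] * h
  }
  cc <- grid$coords
  off <- (n_det + 1) / 2
  img <- matrix(0, grid$n, grid$n)
  dth <- pi / length(angles)
  cs <- cos(angles); sn <- sin(angles)
  for (ix in seq_len(grid$n)) {
    for (iy in seq_len(grid$n)) {
      g <- (cc[ix] * cs + cc[iy] * sn) / h + off
      i0 <- floor(g)
      fr <- g - i0
      v <- numeric(length(angles))
      ok <- i0 >= 1 & i0 <= n_det
      v[ok] <- filt[cbind(i0[ok], which(ok))] * (1 - fr[ok])
      ok1 <- i0 + 1 >= 1 & i0 + 1 <= n_det
      v[ok1] <- v[ok1] + filt[cbind(i0[ok1] + 1, which(ok1))] * fr[ok1]
      img[ix, iy] <- sum(v) * dth
    }
  }
  img
}
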