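test_that("FWHM operator recovers rect widths and Gaussian widths", {
  grid <- image_grid(128, 500)
  pos <- grid$coords
  h <- grid$spacing
  # ideal rectangular profile rendered with partial-volume edges: FWHM
  # recovers the width to within half a pixel (exact when edges are clean)
  for (w_px in c(8, 20, 31)) {
    w <- w_px * h
    prof <- pmax(0, pmin(pos + h / 2, w / 2) - pmax(pos - h / 2, -w / 2)) / h
    img <- matrix(rep(prof, grid$n), grid$n, byrow = FALSE)
    expect_lt(abs(profile_fwhm(img, "AP", c(0, 0), grid) - w), h / 2 + 1e-9)
  }
  # Gaussian profile: FWHM = 2*sqrt(2*log(2))*sigma within 2% at sigma >= 3 px
  for (sig_px in c(3, 5, 9)) {
    sig <- sig_px * h
    img <- matrix(rep(exp(-pos^2 / (2 * sig^2)), grid$n), grid$n)
    expect_equal(profile_fwhm(img, "AP", c(0, 0), grid),
                 2 * sqrt(2 * log(2)) * sig, tolerance = 0.02)
  }
})

test_that("FWHM is invariant to intensity offset and scale", {
  grid <- image_grid(96, 480)
  sig <- 4 * grid$spacing
  base <- exp(-grid$coords^2 / (2 * sig^2))
  img <- matrix(rep(base, grid$n), grid$n)   # varies along x -> AP profile
  f0 <- profile_fwhm(img, "AP", c(0, 0), grid)
  expect_equal(profile_fwhm(img * 7.3, "AP", c(0, 0), grid), f0)
  expect_equal(profile_fwhm(img + 0.5, "AP", c(0, 0), grid), f0,
               tolerance = 1e-9)
  expect_equal(profile_fwhm(img * 100 - 40, "AP", c(0, 0), grid), f0,
               tolerance = 1e-9)
  # flat or truncated profiles are undefined
  expect_error(profile_fwhm(matrix(1, 96, 96), "AP", c(0, 0), grid),
               "FWHM undefined")
  # object hanging off the FOV edge has no right half-maximum crossing
  trunc <- matrix(rep(exp(-(grid$coords - 200)^2 / (2 * 60^2)), 96), 96)
  expect_error(profile_fwhm(trunc, "AP", c(200, 0), grid), "FWHM undefined")
})

test_that("residual blur is a plain signed difference", {
  expect_equal(residual_blur(10.6, 7.3), 3.3)
  expect_equal(residual_blur(7.3, 10.6), -3.3)
  expect_equal(residual_blur(5, 5), 0)
})

test_that("difference maps are signed cosine-squared minus EXPO", {
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(difference_map(a, a), matrix(0, 8, 8))
  b <- a - 2
  expect_equal(difference_map(a, b), matrix(2, 8, 8))
  expect_error(difference_map(a, matrix(0, 4, 4)), "congruent")
})

test_that("difference between schemes concentrates near the moving boundary", {
  grid <- image_grid(64, 500)
  geom <- fast_geom(pitch = 0.10, ppr = 180L)
  bp <- 6
  wf <- generate_waveform("sinusoidal", 10, 30, 3 * bp + 0.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 3 * bp, grid)
  sino <- filter_sinogram(assign_phases(sino, 10L))
  budget <- gating_budget(geom, bp)
  dm <- difference_map(reconstruct_phase(sino, 2, "cosine_squared", budget),
                       reconstruct_phase(sino, 2, "expo", budget))
  # the largest |difference| pixels lie within 2 excursions of the boundary
  hot <- which(abs(dm) >= 0.3 * max(abs(dm)), arr.ind = TRUE)
  x <- grid$coords[hot[, 1]]
  y <- grid$coords[hot[, 2]]
  r <- sqrt((x - (-80))^2 + y^2)       # distance to object center
  band <- abs(r - 27) <= 60            # radius 27 mm, band of 2x excursion
  expect_gt(mean(band), 0.95)
})

test_that("ROI statistics report mean, sd, n and reject empty ROIs", {
  grid <- image_grid(64, 500)
  img <- matrix(5, 64, 64)
  rois <- list(list(label = "c", center = c(0, 0), radius = 40),
               list(label = "r", center = c(100, -50), extent = c(60, 40)))
  st <- roi_stats(img, rois, grid)
  expect_equal(st$mean, c(5, 5))
  expect_equal(st$sd, c(0, 0))
  expect_true(all(st$n_pixels >= 25))
  expect_error(roi_stats(img, list(list(label = "out", center = c(400, 400),
                                        radius = 2)), grid), "empty ROI")
})

test_that("a small static blur sweep yields ~zero residuals everywhere", {
  suite <- standard_phantom_suite("static_truth")
  report <- blur_sweep(suite, schemes = "cosine_squared",
                       grid = image_grid(64, 500),
                       geom_template = fast_geom(pitch = 0.10, ppr = 180L),
                       configs = data.frame(bpm = 12, pitch = 0.10),
                       cycles = 3)
  expect_true(all(c("object_id", "motion_axis", "bpm", "pitch", "phase",
                    "scheme", "fwhm_mm", "static_mm", "residual_mm")
                  %in% names(report)))
  expect_equal(nrow(report), 2 * 10)   # 2 moving-capable objects x 10 phases
  half_px <- 500 / 64 / 2
  expect_true(all(abs(report$residual_mm) <= half_px))
  s <- summary(report)
  expect_equal(s$n, 20)
  expect_lt(abs(s$mean_residual_mm), half_px)
})
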