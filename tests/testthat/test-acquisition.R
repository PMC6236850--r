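test_that("forward projection agrees with the brute-force ray-sum oracle", {
  grid <- image_grid(64, 500)
  img <- phantom_at_time(list(
    phantom_object("disk", c(-50, 30), 60, 0.02),
    phantom_object("rectangle", c(70, -40), c(80, 40), 0.01)
  ), NULL, 0, grid)
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  fast <- project_image(img, grid, angles)
  slow <- oracle_project(img, grid, angles)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-6)
})

test_that("acquisition of a static phantom is rotation-periodic and deterministic", {
  grid <- image_grid(48, 500)
  geom <- fast_geom(ppr = 90L)
  wf <- generate_waveform("sinusoidal", 60, 30, 2.5)
  ph <- static_test_phantom()
  s1 <- acquire(ph, wf, geom, 2, grid)
  s2 <- acquire(ph, wf, geom, 2, grid)
  expect_identical(s1$data, s2$data)
  ppr <- geom$projections_per_rotation
  expect_equal(s1$data[, 1:ppr], s1$data[, ppr + (1:ppr)], tolerance = 1e-12)
  # and equals the line-integral transform of the static image
  img <- phantom_at_time(ph, wf, 0, grid)
  direct <- project_image(img, grid, s1$angles[1:5])
  expect_equal(s1$data[, 1:5], direct, tolerance = 1e-12)
  # empty phantom gives an all-zero sinogram
  ph0 <- list(phantom_object("disk", c(0, 0), 10, 0))
  expect_equal(max(abs(acquire(ph0, wf, geom, 2, grid)$data)), 0)
})

test_that("shift-theorem assembly matches direct per-time projection", {
  grid <- image_grid(48, 500)
  geom <- fast_geom(ppr = 60L)
  wf <- generate_waveform("sinusoidal", 30, 30, 4.5)
  ph <- moving_test_phantom()
  fast <- acquire(ph, wf, geom, 4, grid, method = "shift")
  slow <- acquire(ph, wf, geom, 4, grid, method = "direct")
  # the two discretizations smooth sharp edges slightly differently, so
  # compare the field as RMSE and the encoded motion as detector centroids
  scale <- max(abs(slow$data))
  expect_lt(sqrt(mean((fast$data - slow$data)^2)) / scale, 0.02)
  com_fast <- colSums(fast$data * grid$coords) / colSums(fast$data)
  com_slow <- colSums(slow$data * grid$coords) / colSums(slow$data)
  expect_lt(max(abs(com_fast - com_slow)) / grid$spacing, 0.05)
})

test_that("noise is seeded and additive", {
  grid <- image_grid(32, 500)
  geom <- fast_geom(ppr = 60L)
  wf <- generate_waveform("sinusoidal", 60, 30, 2.5)
  ph <- static_test_phantom()
  clean <- acquire(ph, wf, geom, 2, grid)
  n1 <- acquire(ph, wf, geom, 2, grid, noise_sigma = 0.01, seed = 5)
  n2 <- acquire(ph, wf, geom, 2, grid, noise_sigma = 0.01, seed = 5)
  n3 <- acquire(ph, wf, geom, 2, grid, noise_sigma = 0.01, seed = 6)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))
  resid <- n1$data - clean$data
  expect_equal(sd(as.numeric(resid)), 0.01, tolerance = 0.02)
  expect_equal(mean(resid), 0, tolerance = 1e-3)
})

test_that("peak detection finds sinusoid maxima and refines sub-sample", {
  t <- seq(0, 12, by = 0.05)
  pk <- peak_detect(sin(2 * pi * t / 4), t)
  expect_equal(pk, c(1, 5, 9), tolerance = 0.05)
  expect_length(peak_detect(seq(0, 1, length.out = 100),
                            seq(0, 1, length.out = 100)), 0)
  expect_identical(peak_detect(sin(2 * pi * t / 4), t),
                   peak_detect(sin(2 * pi * t / 4), t))
})

test_that("phase tags follow the peak-fraction convention", {
  grid <- image_grid(32, 500)
  geom <- fast_geom(ppr = 120L)
  bp <- 4
  wf <- generate_waveform("sinusoidal", 60 / bp, 30, 3 * bp + 0.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 3 * bp, grid)
  sino <- assign_phases(sino, 10L)
  # projection nearest a surrogate peak lands in bin 0
  k_peak <- which.min(abs(sino$times - bp / 4))
  expect_equal(sino$phase_bin[k_peak], 0L)
  expect_lt(min(abs(c(sino$phase_fraction[k_peak],
                      1 - sino$phase_fraction[k_peak]))), 0.01)
  # half a cycle later is end-exhale, bin 5 of 10
  k_ee <- which.min(abs(sino$times - (bp / 4 + bp / 2)))
  expect_equal(sino$phase_bin[k_ee], 5L)
  # long acquisition: each bin receives ~10% of projections
  frac <- as.numeric(table(factor(sino$phase_bin, levels = 0:9))) /
    length(sino$phase_bin)
  expect_true(all(abs(frac - 0.1) < 0.01))
})

test_that("phase tags are invariant to a constant surrogate offset", {
  grid <- image_grid(32, 500)
  geom <- fast_geom(ppr = 120L)
  wf <- generate_waveform("sinusoidal", 15, 30, 12.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 12, grid)
  a <- assign_phases(sino, 10L)
  sino$waveform$surrogate <- sino$waveform$surrogate + 3.7
  b <- assign_phases(sino, 10L)
  expect_identical(a$phase_bin, b$phase_bin)
  expect_equal(a$phase_fraction, b$phase_fraction)
})

test_that("sinusoid phase bins k and 10-k see mirror-symmetric displacements", {
  grid <- image_grid(32, 500)
  geom <- fast_geom(ppr = 120L)
  bp <- 4
  wf <- generate_waveform("sinusoidal", 60 / bp, 30, 6 * bp + 0.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 6 * bp, grid)
  sino <- assign_phases(sino, 10L)
  disp <- waveform_displacement(wf, sino$times)
  for (k in c(1, 2, 3, 4)) {
    dk <- sort(disp[sino$phase_bin == k])
    dm <- sort(disp[sino$phase_bin == (10 - k) %% 10])
    expect_equal(mean(dk), mean(dm), tolerance = 0.5)
    expect_equal(stats::quantile(dk, c(.25, .5, .75)),
                 stats::quantile(dm, c(.25, .5, .75)), tolerance = 1.5)
  }
  # too few peaks cannot be phase-sorted
  short <- acquire(moving_test_phantom(),
                   generate_waveform("sinusoidal", 60 / bp, 30, 2 * bp + 0.5),
                   geom, 2 * bp, grid)
  short$waveform$surrogate <- rep(0, length(short$waveform$surrogate))
  expect_error(assign_phases(short, 10L), "cannot phase-sort")
})
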