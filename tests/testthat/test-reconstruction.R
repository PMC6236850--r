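# Shared fixture: static phantom under a slow waveform that violates the
# breathing-period condition, so the gating window is widened and the
# temporal weights actually engage.
grid <- image_grid(64, 500)
rec_budget <- gating_budget(fast_geom(pitch = 0.10, ppr = 180L), 5)
rec_static_sino <- {
  geom <- fast_geom(pitch = 0.10, ppr = 180L)       # bound ~2.8 s; BP 5 violates
  wf <- generate_waveform("sinusoidal", 12, 30, 15.5)
  sino <- acquire(static_test_phantom(), wf, geom, 15, grid)
  filter_sinogram(assign_phases(sino, 10L))
}

test_that("static weighted reconstruction matches textbook FBP", {
  expect_gt(rec_budget$window_widening, 0)
  img_c <- reconstruct_phase(rec_static_sino, 0, "cosine_squared", rec_budget)
  # oracle: plain half-rotation FBP of the static sinogram
  ppr <- rec_static_sino$geometry$projections_per_rotation
  half <- ppr / 2
  oracle <- oracle_fbp(rec_static_sino$data[, 1:half],
                       rec_static_sino$angles[1:half], grid)
  contrast <- 0.019
  rmse <- sqrt(mean((img_c$pixels - oracle)^2))
  expect_lt(rmse / contrast, 0.01)
  # reconstruction recovers the object attenuation reasonably
  ix <- which.min(abs(grid$coords + 80))
  iy <- which.min(abs(grid$coords))
  expect_equal(img_c$pixels[ix, iy], 0.019, tolerance = 0.05)
})

test_that("weighting schemes agree on static data after normalization", {
  img_c <- reconstruct_phase(rec_static_sino, 3, "cosine_squared", rec_budget)
  img_e <- reconstruct_phase(rec_static_sino, 3, "expo", rec_budget)
  expect_lt(max(abs(img_c$pixels - img_e$pixels)), 1e-6)
  # all phases of a static phantom are essentially identical
  p0 <- reconstruct_phase(rec_static_sino, 0, "expo", rec_budget)
  p5 <- reconstruct_phase(rec_static_sino, 5, "expo", rec_budget)
  expect_lt(max(abs(p0$pixels - p5$pixels)), 1e-6)
})

test_that("at the half-rotation minimum both schemes degrade to uniform, bit-identical", {
  grid2 <- image_grid(48, 500)
  geom <- fast_geom(pitch = 0.10, ppr = 120L)
  bp <- 2.4                                   # satisfies the condition
  budget <- gating_budget(geom, bp)
  expect_equal(budget$window_widening, 0)
  expect_identical(budget$window_projection_count,
                   budget$minimum_projection_count)
  wf <- generate_waveform("sinusoidal", 60 / bp, 30, 3 * bp + 0.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 3 * bp, grid2)
  sino <- filter_sinogram(assign_phases(sino, 10L))
  img_c <- reconstruct_phase(sino, 2, "cosine_squared", budget)
  img_e <- reconstruct_phase(sino, 2, "expo", budget)
  expect_identical(img_c$pixels, img_e$pixels)
  expect_equal(length(img_c$window_indices), 60)
  expect_equal(img_c$scheme_used, "uniform")
})

test_that("window selection centers the phase point and respects the budget", {
  w <- select_window(rec_static_sino, 4, rec_budget)
  expect_length(w$indices, rec_budget$window_projection_count)
  expect_true(all(diff(w$indices) == 1))
  d <- abs(rec_static_sino$phase_fraction[w$center_index] - 0.4)
  expect_lt(min(d, 1 - d), 1 / 20)
  # larger breathing period -> longer window
  b2 <- gating_budget(rec_static_sino$geometry, 6)
  expect_gt(b2$window_projection_count, rec_budget$window_projection_count)
  # absurdly long window cannot fit
  b3 <- rec_budget
  b3$window_projection_count <- ncol(rec_static_sino$data) + 100L
  expect_error(select_window(rec_static_sino, 0, b3),
               "insufficient acquisition duration")
})

test_that("ten-phase reconstruction separates motion extremes by the excursion", {
  grid2 <- image_grid(64, 500)
  geom <- fast_geom(pitch = 0.10, ppr = 180L)
  bp <- 5
  wf <- generate_waveform("sinusoidal", 60 / bp, 30, 3 * bp + 0.5)
  sino <- acquire(moving_test_phantom(), wf, geom, 3 * bp, grid2)
  phases <- reconstruct_4dct(sino, 10L, "expo")
  expect_length(phases, 10)
  expect_true(all(vapply(phases, inherits, logical(1), "phase_image")))
  com_y <- vapply(phases, function(p) {
    ix <- which(grid2$coords > -140 & grid2$coords < -20)
    m <- pmax(p$pixels[ix, ] - 0.001, 0)
    sum(t(m) * grid2$coords) / sum(m)
  }, numeric(1))
  # end-inhale (phase 0) and end-exhale (phase 5) centroids ~ excursion apart
  expect_equal(abs(com_y[1] - com_y[6]), 30, tolerance = 3)
})

test_that("derivative images obey min <= avg <= max and degenerate cases", {
  a <- matrix(1, 4, 4); b <- matrix(3, 4, 4)
  d <- derivative_images(list(a, b))
  expect_equal(d$mip, b)
  expect_equal(d$minip, a)
  expect_equal(d$avg, matrix(2, 4, 4))
  one <- derivative_images(list(a))
  expect_equal(one$mip, a)
  expect_equal(one$minip, a)
  expect_equal(one$avg, a)
  set.seed(3)
  imgs <- replicate(5, matrix(rnorm(16), 4, 4), simplify = FALSE)
  d2 <- derivative_images(imgs)
  expect_true(all(d2$minip <= d2$avg & d2$avg <= d2$mip))
  expect_error(derivative_images(list(a, matrix(0, 3, 3))), "mismatch")
})

test_that("HU conversion anchors water, air and double-water", {
  expect_equal(to_hu(matrix(0.019, 2, 2))[1, 1], 0)
  expect_equal(to_hu(matrix(0, 2, 2))[1, 1], -1000)
  expect_equal(to_hu(matrix(0.038, 2, 2))[1, 1], 1000)
  expect_error(to_hu(matrix(1, 2, 2), mu_water = 0))
})
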