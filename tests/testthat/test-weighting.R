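test_that("cosine-squared weight matches its closed form", {
  it <- 64
  im <- 33
  expect_equal(cosine_squared_weight(im, im, it), 1)
  expect_equal(cosine_squared_weight(im + it / 2, im, it), 0, tolerance = 1e-12)
  expect_equal(cosine_squared_weight(im - it / 2, im, it), 0, tolerance = 1e-12)
  expect_equal(cosine_squared_weight(im + it / 4, im, it), 0.5)
  expect_equal(cosine_squared_weight(im - it / 4, im, it), 0.5)
  # outside the window the projection is not used
  expect_equal(cosine_squared_weight(im + it, im, it), 0)
  # symmetry about the mid-phase point
  off <- 1:31
  expect_equal(cosine_squared_weight(im + off, im, it),
               cosine_squared_weight(im - off, im, it))
})

test_that("exponential term matches its closed form and monotonicities", {
  it <- 100
  ih <- 50
  expect_equal(exponential_term(ih, ih, it, 2), 1)
  expect_equal(exponential_term(ih + it, ih, it, 2), exp(-2))
  expect_equal(exponential_term(ih + it, ih, it, 2), 0.135335, tolerance = 1e-5)
  # steepness zero degenerates to one everywhere
  expect_equal(exponential_term(0:200, ih, it, 0), rep(1, 201))
  # strictly decreasing away from the center
  v <- exponential_term(ih + 0:40, ih, it, 2)
  expect_true(all(diff(v) < 0))
  # pointwise decreasing in steepness
  expect_true(all(exponential_term(ih + 1:40, ih, it, 3) <
                  exponential_term(ih + 1:40, ih, it, 2)))
})

test_that("EXPO weight is the product form and is dominated by cosine-squared", {
  it <- 64
  im <- 33
  expect_equal(expo_weight(im, im, it), 1)
  expect_equal(expo_weight(im + it / 4, im, it, steepness = 2),
               0.5 * exp(-0.5))
  expect_equal(expo_weight(im + it / 4, im, it, steepness = 2), 0.303265,
               tolerance = 1e-5)
  expect_equal(expo_weight(im + it / 2, im, it), 0, tolerance = 1e-12)
  # pointwise domination for every nonnegative steepness, equality at center
  i <- seq(im - it / 2, im + it / 2)
  for (ef in c(0.5, 1, 2, 4, 8)) {
    we <- expo_weight(i, im, it, steepness = ef)
    wc <- cosine_squared_weight(i, im, it)
    expect_true(all(we <= wc + 1e-15))
    expect_lt(max(we[i != im] - wc[i != im]), 0)
  }
  expect_equal(expo_weight(i, im, it, steepness = 0),
               cosine_squared_weight(i, im, it))
})

test_that("weight curves are symmetric, peaked at mid-phase, converge as steepness -> 0", {
  for (it in c(33, 64, 181)) {
    for (scheme in c("cosine_squared", "expo")) {
      wc <- build_weight_curve(it, scheme)
      expect_length(wc$weights, it)
      expect_true(all(wc$weights >= 0 & wc$weights <= 1))
      expect_equal(which.max(wc$weights), wc$mid_phase_index)
      im <- wc$mid_phase_index
      reach <- min(im - 1, it - im)
      expect_equal(wc$weights[im + seq_len(reach)],
                   wc$weights[im - seq_len(reach)])
    }
  }
  expect_equal(build_weight_curve(1, "expo")$weights, 1)
  expect_equal(build_weight_curve(97, "expo", steepness = 0)$weights,
               build_weight_curve(97, "cosine_squared")$weights)
  expect_equal(build_weight_curve(64, "expo", steepness = 1e-9)$weights,
               build_weight_curve(64, "cosine_squared")$weights,
               tolerance = 1e-8)
  expect_equal(build_weight_curve(5, "uniform")$weights, rep(1, 5))
})

test_that("effective temporal width: closed forms and strict shrink with steepness", {
  expect_equal(effective_temporal_width(build_weight_curve(40, "uniform")), 40)
  # cosine-squared half-maximum sits at quarter-window offsets
  expect_equal(effective_temporal_width(build_weight_curve(64, "cosine_squared")),
               32)
  expect_equal(effective_temporal_width(build_weight_curve(128, "cosine_squared")),
               64)
  widths <- vapply(c(0, 1, 2, 4, 8), function(ef) {
    effective_temporal_width(build_weight_curve(128, "expo", steepness = ef))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3],
            effective_temporal_width(build_weight_curve(128, "cosine_squared")))
})

test_that("redundancy-group normalization sums to one and preserves order", {
  wc <- build_weight_curve(12, "uniform")
  groups <- rep(1:3, each = 4)
  nc <- normalize_weights(wc, groups)
  expect_equal(as.numeric(tapply(nc$normalized, groups, sum)), rep(1, 3))
  expect_equal(nc$normalized, rep(0.25, 12))
  # singleton groups always get weight one
  wc2 <- build_weight_curve(5, "expo")
  nc2 <- normalize_weights(wc2, 1:5)
  expect_equal(nc2$normalized, rep(1, 5))
  # relative ordering within a group survives
  wc3 <- build_weight_curve(8, "expo")
  nc3 <- normalize_weights(wc3, rep(1, 8))
  expect_equal(order(nc3$normalized), order(wc3$weights))
  expect_equal(sum(nc3$normalized), 1)
  # a group with no usable weight is an error
  wc4 <- build_weight_curve(4, "cosine_squared")
  wc4$weights <- c(0, 0, 1, 1)
  expect_error(normalize_weights(wc4, c(1, 1, 2, 2)), "insufficient data")
})

test_that("weight curve CSV export round-trips", {
  wc <- normalize_weights(build_weight_curve(16, "expo"), rep(1:8, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  export_weight_curve(wc, f)
  df <- read.csv(f)
  expect_equal(df$raw_weight, wc$weights)
  expect_equal(df$normalized_weight, wc$normalized)
})
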