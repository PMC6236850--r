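# Shared small fixtures, built in code.

# geometry with few projections for fast reconstruction tests
fast_geom <- function(pitch = 0.10, ppr = 180L) {
  scanner_geometry(570, 500, 24, 0.5, pitch, ppr)
}

# small static phantom (objects do not move even under a live waveform)
static_test_phantom <- function() {
  list(
    phantom_object("rectangle", c(0, 0), c(360, 220), 0.0005, "none"),
    phantom_object("disk", c(-80, 0), 54, 0.019, "none"),
    phantom_object("disk", c(80, 0), 36, 0.019, "none")
  )
}

# one moving disk on a slab
moving_test_phantom <- function(excursion = 30) {
  list(
    phantom_object("rectangle", c(0, 0), c(360, 220), 0.0005, "none"),
    phantom_object("disk", c(-80, 0), 54, 0.019, "SI", excursion)
  )
}

# acquire a phase-tagged, filtered sinogram in one call
tagged_sinogram <- function(phantom, bpm, geom, grid, cycles = 3,
                            noise_sigma = 0, seed = 1L) {
  bp <- 60 / bpm
  wf <- generate_waveform("sinusoidal", bpm, 30, cycles * bp + 0.5)
  sino <- acquire(phantom, wf, geom, cycles * bp, grid,
                  noise_sigma = noise_sigma, seed = seed)
  assign_phases(sino, 10L)
}

random_valid_geometry <- function() {
  rs <- stats::runif(1, 400, 800)
  scanner_geometry(
    source_isocenter_distance = rs,
    fov = stats::runif(1, 100, min(2 * rs - 1, 900)),
    collimation = stats::runif(1, 5, 60),
    rotation_time = stats::runif(1, 0.3, 1.5),
    pitch = stats::runif(1, 0.03, 0.3),
    projections_per_rotation = sample(c(180L, 360L, 720L), 1)
  )
}
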