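# expo4dct

A desk-scale virtual 4DCT system for studying **temporal gating-window
weighting** in respiration-correlated CT, written for medical-physics and
reconstruction researchers who want the mechanism on their desk rather
than on a scanner.

Retrospectively gated 4DCT sorts projections by respiratory phase. When
the helical pitch is not low enough to keep every voxel illuminated for a
whole breathing cycle — i.e. when the breathing period exceeds

    BP_max = (1 - FOV / 2R_S) * RT / PF,

the reconstruction widens each phase's temporal gate by
`Tw = BP - BP_max` seconds beyond the half-rotation minimum of
projections. The temporally distant projections in the widened gate blur
moving boundaries. Two tapers across the gate of `It` projections with
mid-phase point `Im` are implemented:

    cos^2 weighting:  w(i) = cos^2( pi * (i - Im) / It )
    EXPO weighting:   w(i) = cos^2( pi * (i - Im) / It ) * exp( -|i - Ih| * Ef / It )

with `Ef = 2` the fixed clinical default and `Ih = Im`. EXPO suppresses
temporally distant projections harder, sharpening moving boundaries at
the cost of slightly higher image noise.

The package provides the full pipeline: acquisition temporal budget
(visibility length, transit time, breathing-period/pitch conditions,
window widening), digital motion phantoms under sinusoidal / sawtooth /
irregular respiratory waveforms, time-stamped parallel-beam sinogram
simulation, surrogate peak detection and ten-phase retrospective sorting,
weighted filtered backprojection with conjugate-ray weight normalization,
derivative images (MIP / minIP / average CT), and quantitative evaluation
(FWHM residual motion blur, difference maps, ROI noise statistics).

## Worked example

Budget first: at pitch 0.10 and 10 bpm breathing (period 6 s) the
breathing-period condition is violated and the gate grows far beyond the
half-rotation minimum:

```r
library(expo4dct)
geom <- scanner_geometry(source_isocenter_distance = 570, fov = 500,
                         collimation = 24, rotation_time = 0.5,
                         pitch = 0.10, projections_per_rotation = 360L)
budget <- gating_budget(geom, breathing_period = 6)
print(budget)
#> Gating budget
#>   breathing period    : 6 s (bound 2.807 s; condition violated)
#>   visibility length   : 13.47 mm
#>   couch velocity      : 4.8 mm/s
#>   window widening Tw  : 3.193 s
#>   window projections  : 2479 (minimum 180)

wc <- build_weight_curve(budget$window_projection_count, "cosine_squared")
we <- build_weight_curve(budget$window_projection_count, "expo")
effective_temporal_width(wc)   # 1239 projections (It/2)
effective_temporal_width(we)   # 888 projections: EXPO's sharper gate
```

Then the motion-platform experiment: two soft-tissue disks moving
superior-inferior with 30 mm excursion, acquired, phase-sorted into ten
bins and reconstructed with both weightings; residual blur is each
object's profile FWHM minus its static-truth FWHM:

```r
suite  <- standard_phantom_suite("si_sinusoid_grid")
report <- blur_sweep(suite, grid = image_grid(128, 500),
                     geom_template = geom,
                     configs = data.frame(bpm = 10, pitch = 0.10), seed = 1)
summary(report)
#>           scheme mean_residual_mm sd_residual_mm min_residual_mm max_residual_mm  n
#> 1 cosine_squared           0.0648          0.241          -0.268           0.484 20
#> 2           expo          -0.0143          0.161          -0.287           0.234 20
```

The cosine-squared minus EXPO blur gap per phase peaks at the
transitional phases (2-3 and 7-8), where the platform moves fastest, and
vanishes at the breathing extremes (phases 0 and 5):

```r
#>     0     1     2     3     4     5     6     7     8     9
#> 0.025 0.033 0.153 0.153 0.033 0.025 0.033 0.152 0.152 0.033   (mm)
```

At high breathing rates the gate stays at its half-rotation minimum, no
weighting is employed, and both schemes return bit-identical images. With
projection noise, the EXPO background ROI standard deviation exceeds the
cosine-squared one in every matched-seed pair (ratio ~1.02 at these
sizes) while ROI means agree to well under 1 HU.

A thin CLI over the same functions lives at `inst/cli/expo4dct`
(`simulate` / `reconstruct` / `analyze` / `suite` subcommands, YAML
configs, NIfTI + CSV outputs).

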