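---
title: "Exponential-weighted 4DCT reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential-weighted 4DCT reconstruction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expo4dct)
```

## The problem

Respiration-correlated CT (4DCT) reconstructs one image per breathing
phase by retrospectively sorting projections according to a respiratory
surrogate. When a low-pitch helical acquisition cannot keep every voxel
illuminated for a full breathing cycle, the reconstruction must widen the
temporal gating window of each phase beyond the half-rotation minimum of
projections. The extra, temporally distant projections are redundant: they
see the anatomy at the wrong part of the breathing cycle and blur moving
boundaries. The conventional remedy is a cosine-squared taper across the
window; this package implements and evaluates a sharper alternative — the
cosine-squared taper multiplied by a decaying exponential (EXPO) — inside
a fully synthetic, desk-scale 4DCT system, so that the central trade-off
(sharper moving boundaries at the cost of slightly higher noise) can be
reproduced and dissected in simulation.

## Acquisition temporal budget

For a source-isocenter distance $R_S$, field of view $FOV$, collimation
$COLL$, rotation time $RT$ and pitch $PF$:

* visibility length at the FOV edge: $Z_m = (R_S - FOV/2)\,COLL / R_S$;
* couch velocity $V = PF \cdot COLL / RT$ and transit time $TT = Z_m / V$;
* full illumination over a breathing period $BP$ requires
  $BP \le (1 - FOV/2R_S)\, RT / PF$ (equivalently a pitch bound at fixed
  $BP$); $TT$ equals this bound identically, which the tests exploit;
* when violated, the temporal gate grows by
  $T_w = BP - RT/PF\,(1 - FOV/2R_S)$ seconds.

Design choices where the source system is under-specified:

* $T_w$ is clamped at zero when the condition holds — negative widening is
  unphysical, and the derivation only covers the violated case.
* $T_w$ is converted to a projection count at the scanner's uniform
  angular sampling rate: $I_t = \lceil PPR/2 + T_w \cdot PPR/RT\rceil$,
  never below the half-rotation minimum $PPR/2$. How a vendor discretizes
  the widened gate is not public; a linear mapping is the natural choice.
* The "half-rotation minimum" is exact here because the projector is
  parallel-beam: 180 degrees of parallel data is complete.
* Both bounds are treated as non-strict inequalities.

## Temporal weighting

Across a gating window of $I_t$ projections with mid-phase index $I_m$,

$$w_{\cos^2}(i) = \cos^2\!\big(\pi (i - I_m)/I_t\big), \qquad
  w_{EXPO}(i) = w_{\cos^2}(i)\; e^{-|i - I_h|\,E_f/I_t},$$

with $E_f = 2$ the fixed clinical default and $I_h = I_m$ by default.
Three notational ambiguities in the source material were resolved as
package design choices:

* the $\pi$ factor is used in the cosine for **both** schemes, so the
  taper vanishes exactly at the gate edges (a cosine window that stays
  positive at the boundary contradicts the intended gating behavior);
* the exponential is centered on the mid-phase point ($I_h = I_m$); a
  peak at the window end would defeat the purpose of sharpening around
  the reconstruction phase point. $I_h$ remains a parameter;
* the exponent groups as $|i-I_h| \cdot E_f / I_t$, so that larger $E_f$
  is steeper.

Raw weights are then **normalized within conjugate-ray redundancy
groups**: projections half a rotation apart measure the same parallel ray
(with a detector flip), and within each such group the weights are
rescaled to sum to one. This is required for an unbiased reconstruction
and mirrors the standard practice in gated reconstruction. A consequence
worth noting: normalization flattens much of the raw taper (each ray's
members compete only against each other), so the residual sharpening
effect of EXPO is modest per ray but systematic across rays.

When the gating window is at its half-rotation minimum every ray is
measured exactly once, weighting cannot redistribute anything, and the
implementation forces the `uniform` scheme — reconstructions under either
weighting are then bit-identical, which is asserted in the tests.

The package quantifies the "sharper slope" claim via
`effective_temporal_width()`, the FWHM of the weight curve: $I_t/2$ for
cosine-squared, strictly less for EXPO at any positive steepness.

## The virtual scanner

* **2-D axial slices, parallel-beam.** The weighting acts on the temporal
  axis and is geometry-agnostic; parallel geometry gives an exact
  half-rotation completeness condition. Superior-inferior motion is
  represented as in-plane translation, and blur is measured along the
  motion axis, as in the physical experiment the package emulates.
* **Pitch enters only through the temporal budget.** The couch is not
  geometrically simulated; helical cone-beam ray geometry is out of
  scope. This is the central desk-scale simplification: pitch and
  breathing rate determine $T_w$ and hence the window length, which is
  exactly the mechanism the weighting schemes act on. Absolute blur
  magnitudes are therefore much smaller than on a physical scanner,
  where helical interpolation mixes anatomy from different couch
  positions; all evaluation claims are directional.
* **Forward model.** Projections are ray-driven line integrals with
  bilinear sampling at half-pixel steps. Because every phantom object
  translates rigidly, the acquisition assembles each time point from
  per-motion-group static sinograms shifted along the detector by
  $d\cdot(\cos\theta, \sin\theta)$ (the parallel-beam shift theorem) —
  exact for the continuous phantom up to the linear detector
  interpolation, and two orders of magnitude faster than re-projecting
  every time step. The slow per-time-step path (`method = "direct"`) is
  kept for cross-checking, and a brute-force ray-sum oracle validates the
  projector in the tests.
* **Noise** is zero-mean Gaussian on the line integrals with configurable
  standard deviation, seeded. Poisson counting statistics, scatter, beam
  hardening and detector effects are not modeled; additive Gaussian noise
  is sufficient to exhibit (and rank) the noise amplification of a more
  concentrated weight curve, which scales with $\sum_i \tilde w_i^2$ per
  ray.
* **Reconstruction** is filtered backprojection with the band-limited
  spatial-domain ramp kernel (optional Hann apodization, off by default),
  linear detector interpolation, and the per-ray weight normalization
  above. The gating window is a single contiguous run of projections
  centered on the phase point (the projection whose phase fraction is
  nearest the bin center; earliest wins ties, and candidates are
  restricted to positions where the window fits). Pooling a phase's
  projections across multiple breathing cycles is deliberately not done.

## Respiratory model and phase sorting

Waveforms are sampled at 100 Hz and carry a unitless surrogate (the
bellows-belt analog) plus a displacement trace in mm with peak-to-peak
amplitude as configured; the surrogate exists even for a zero-amplitude
static acquisition, so static scans still phase-sort. Supported shapes:

* *sinusoidal* — the motion-platform default;
* *sawtooth* — linear descent over 90% of the cycle with a rapid 10%
  reset; the duty cycle is a package choice (the source protocol does not
  state one);
* *irregular* — per-cycle period and amplitude scaled by
  $1 + \mathrm{irregularity}\cdot U(-1,1)$ from a seeded generator,
  a deliberately simple caricature of irregular breathers.

Phase sorting detects surrogate maxima (local maxima above a fractional
prominence threshold, refined by quadratic sub-sample interpolation) and
assigns each projection the elapsed fraction of its peak-to-peak
interval. Bins are centered: bin $k$ of $n$ covers fractions
$[k/n - 1/2n,\ k/n + 1/2n)$, so bin 0 is centered on end-inhale and bin
$n/2$ on end-exhale for symmetric waveforms.

## Phantom suites

`standard_phantom_suite()` reproduces the motion-platform factorials: a
lung-mimicking low-attenuation slab carrying soft-tissue disks, moved
with 30 mm peak-to-peak excursion:

* `si_sinusoid_grid` — two disks (54 mm and 36 mm diameter) moving
  superior-inferior; breathing rates 10, 12, 15, 20 bpm crossed with
  pitches 0.06, 0.08, 0.10. The disk diameters approximate the reported
  static FWHMs of the physical inserts (54.4 and 36.7 mm); the exact
  sizes and contrasts of those inserts are not published.
* `ap_sawtooth_grid` — one small 8 mm high-contrast disk moving
  anterior-posterior; rates 8, 10, 12 bpm, same pitches.
* `static_truth` — the SI phantom under a zero-amplitude waveform.

Scanner defaults: $R_S = 570$ mm, $FOV = 500$ mm, $COLL = 24$ mm,
$RT = 0.5$ s. What the generator does **not** emulate: real anatomy and
tissue heterogeneity, bellows sensor noise, breathing drift and
amplitude-phase decoupling, 3-D geometry. Passing tests therefore show
that the weighting mechanism behaves as claimed under controlled rigid
motion, not that clinical images would show effects of the same size.

## Blur metric

Residual blur is the FWHM of a 1-D profile through the object's known
center along its motion axis, minus the object's FWHM on the matched
static-truth reconstruction (not its nominal diameter, so the
reconstruction kernel cancels). Conventions, chosen where the cited
measurement procedure leaves detail open:

* background level = median of the outer 20% of profile samples;
* half-maximum crossings located by linear interpolation only (no
  splines), for determinism; the measure is invariant to intensity offset
  and scale;
* profiles pass through the static centroid, fixed across phases, so the
  placement does not chase motion blur;
* residuals are reported unclamped and can be slightly negative: the
  moving-window reconstructions carry a small (~0.1 px) systematic FWHM
  offset against the full-rotation static reference, and a sharper
  temporal window can narrow the apparent FWHM marginally below it.

The FWHM of a linearly interpolated sampled profile has a resolution of
about half a pixel, and all equality-style assertions on it use a
half-pixel tolerance. In the suite-level comparison of the two schemes,
rows whose residuals differ by less than half a pixel are accordingly
treated as ties; the strict claims (positive mean cosine-squared minus
EXPO gap at each transitional phase, growth of the gap with pitch, decay
with breathing rate) are asserted on per-phase and per-configuration
means without tolerance.

## Problem sizes used in tests and the acceptance script

The shipped evaluation uses a 128x128 grid over a 500 mm FOV, 360
projections per rotation, 3-cycle acquisitions, ten phases, and a
6-configuration subset of the sinusoid factorial (rates 10, 12, 20 bpm;
pitches 0.06, 0.10 — the rate extremes plus an interior value, and the
pitch extremes); the noise experiment uses 20 matched-seed pairs on a
64x64 grid. These sizes were chosen as the smallest at which the
directional claims are cleanly resolved above the FWHM measurement
resolution; unit tests use 32-64 pixel grids with 60-180 projections per
rotation.

## Known limitations

* Absolute blur magnitudes are not comparable to physical-scanner
  measurements (no helical geometry, no cone angle, rigid 2-D motion).
* Amplitude-based sorting, iterative or motion-compensated
  reconstruction, and vendor kernel replication are out of scope.
* The per-ray normalization is a package choice; the vendor normalization
  is not public.
* With very long gating windows relative to the acquisition, the
  contiguous-window policy can fail to fit; the acquisition must then be
  lengthened (the error message says so).
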