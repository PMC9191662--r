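---
title: "Models and methods behind hemokymo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemokymo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemokymo)
```

`hemokymo` analyses kilohertz two-photon recordings of cortical blood
flow in which the plasma is fluorescent and red blood cells (RBCs) are
dark. This vignette explains the models the package implements, the
choices made where the method was genuinely open, what the synthetic data
do and do not emulate, and the numerical details a careful user should
know.

## The measurement problem

A line-illumination microscope samples a 1D focal array at up to 1 MHz
(all-optical line scanning) and full 2D frames at ~1 kHz. Stacking line
samples in time yields a kymograph — rows are time, columns are space, a
convention fixed everywhere in this package — in which a moving cell
draws a slanted streak. The streak slope in px/line is
`v · 1000 / (pixel_size · line_rate)` for `v` in mm/s. Because velocity
is inferred from displacement between looks, the displacement must stay
below half the array length `h`, giving the measurable-speed bound
`v = f·h/2` (`max_measurable_speed()`).

## Synthetic data as the testing substrate

The simulators are first-class package code, not test scaffolding. They
render:

* **Kymographs** (`simulate_kymograph()`): dark cells of configurable
  length advected along a periodic 1D segment through bright plasma.
  Cells have error-function edges (default softness 0.5 µm) rather than
  hard boundaries, so sub-pixel displacement changes pixel values
  continuously — without this, sub-pixel velocimetry could not be tested.
  Advection uses a left-Riemann cumulative integral of the velocity law
  at line resolution. The noiseless image satisfies
  `mean(I) = background · (1 − contrast · occlusion_fraction)` exactly
  (photon conservation), and the returned ground truth stores the exact
  trajectories.
* **Vessel videos** (`simulate_vessel_video()`): a straight vessel
  segment of radius `R` whose cells move at the blunted-parabola speed of
  their own radial offset (below) times a shared pulsatile modulation
  `1 + Σ_k m_k sin(2π k f0 t)`. Cells re-enter upstream when they leave
  the segment, keeping density stationary, which makes flux truth
  trivial. Radial offsets are drawn uniformly across the open chord of
  the lumen — a chordal, not volumetric, seeding, consistent with the
  in-plane slice the microscope sees. When `2·rbc_radius ≥ 2R` the flow
  is single file and all cells sit at the profile offset `r0`. Rigid
  whole-frame motion, per-column illumination gain, and noise are applied
  after the scene render, in that order.
* **Penetrating-vessel traces** (`simulate_penetrating_trace()`):
  baseline fluorescence minus one negative Gaussian of width σ per
  transit (so both edges of each dip are Gaussian edges of that width),
  with Poisson event times or caller-supplied times; the generator warns
  when the expected gap falls below 4σ, where merged dips are expected.

Noise is Poisson per pixel on the photon-count scale with optional
additive Gaussian read noise, matching photon-limited detection. All
generators are bit-reproducible given a seed.

The line-illumination array runs along frame *columns*: illumination gain
is a per-column profile, and the slow galvo axis is rows. One orientation
is used consistently in the simulator, the normalizers and the tests.

What the simulations do **not** emulate: optical sectioning and
point-spread blur, depth-dependent attenuation, focal-plane drift,
brightness variation of cells moving out of focus, deformable (non-rigid)
tissue motion, and cell–cell hydrodynamic interactions. Passing tests
therefore demonstrate algorithmic correctness against the stated flow
models, not robustness to every imaging pathology of real data. One
consequence worth knowing: because rendered cells have finite size, a
kymograph sampled on a chord near the vessel wall also sees faster cells
whose centres lie closer to the axis, biasing wall velocities upward.
That bias is physical (it exists in real data too); profile tests
therefore use small cells relative to the lumen, and wall-adjacent
offsets are the least trustworthy part of any measured profile.

## Preprocessing

**Illumination normalization.** The per-column gain is estimated from the
data itself: for kymographs, the time-summed trace; for frame stacks, the
column sums of the 10 brightest rows (by row sum) of the time-averaged
image. The trace is rescaled to unit mean over the included columns — the
scale convention is not dictated by the method, and unit mean preserves
overall brightness. Columns that would be boosted more than `boost_cap`
(default 5×) keep their original values and are flagged; all-zero columns
likewise. Because the correction equalizes the very trace it is estimated
from, a second application is an exact no-op on included columns.

**Temporal binning** (`bin_time()`) is a non-overlapping mean with the
trailing remainder dropped and the rate divided accordingly; megahertz
kymographs are typically binned 10× before PIV.

**Rigid registration** (`register_rigid()`) uses Hann-tapered phase
correlation against the time-mean (or a chosen frame), refined to
sub-pixel precision by a matrix-multiply discrete Fourier transform
upsampled 10× in a ±1.5 px neighbourhood of the integer peak. Frames are
resampled bilinearly with replicate padding. Featureless frames (peak
below threshold) get zero shift and a warning. Only whole-frame
translation is corrected; line-by-line (intra-frame) motion is out of
scope.

## 1D velocimetry

`piv_velocity()` correlates each kymograph line with the line `line_lag`
later (default 1), after per-line mean removal and variance
normalization, averages the correlation curves over a window (default
2 ms, advanced by 0.2 ms — five estimates per millisecond), and takes the
argmax displacement with a three-point parabolic sub-pixel fit. The
per-line-pair normalization (rather than one normalization per window)
makes each pair contribute equally regardless of its brightness. Peaks at
the search boundary are reported missing rather than clipped; so are
windows whose peak correlation falls below `min_quality` (default 0.25).
Positive velocity points toward increasing column index, i.e. increasing
arc length of the extraction ROI — reversing an ROI flips the sign.

`radon_velocity()` is the secondary estimator: the window is projected
along candidate streak directions and the direction maximizing the
projection-profile variance wins. Two numerical details matter. The
variance is weighted by bin occupancy, otherwise nearly empty edge bins
dominate; and it is normalized by the bin count, otherwise featureless
noise scores systematically higher at steep angles (the profile of pure
noise has variance proportional to the number of bins). Windows whose
best-to-median score ratio falls below 8 are declared isotropic and
return `NA`. The angle grid is uniform in angle (0.5° coarse, refined
once), which conditions the search better near steep streaks than a
uniform slope grid. The estimator degrades faster than PIV near the
measurable-speed bound — visible in the test suite on noisy synthetic
streaks — which is why PIV is the primary method.

## Dense 2D velocity mapping

`sift_flow()` implements descriptor matching under the truncated-L1
energy shown in the README. Choices:

* **Descriptors**: 4×4 spatial cells × 8 orientation bins of gradient
  magnitude (128 channels), L2-normalized with 0.2 clipping and scaled to
  the conventional 0–255 descriptor range so that the published energy
  weights (η = 0.01, α = 50, d = 10020) are commensurate with the data
  term. Gradient-based descriptors are exactly invariant to additive
  brightness shifts and, after normalization, to global contrast scaling.
* **Data truncation `t`**: not recoverable from any printed value; set
  per frame pair to the 95th percentile of all candidate descriptor
  distances, i.e. an outlier cap that leaves the bulk of the data term
  active. Configurable.
* **Optimization**: frames are up-sampled 2× (cubic) before matching, so
  the integer-displacement solution carries half-pixel precision in
  native units. Minimization is synchronous min-sum loopy belief
  propagation over the joint (u, v) label grid with separable
  truncated-L1 distance-transform messages, damping 0.5, on a 4-connected
  neighbourhood. BP on loopy graphs does not guarantee an energy
  decrease, so the BP labelling is polished by ICM seeded from the better
  of the BP result and the zero field — after which the returned energy
  provably never exceeds the zero-field energy, and constant frames
  return an exactly zero field (the η term breaks the tie). Non-converged
  message passing returns the best labelling found, flagged.
* **Single scale**: a coarse-to-fine pyramid is not implemented
  (`pyramid_levels` only accepts 1). At the problem sizes the package
  targets, the search radius can simply be set to cover the largest
  expected displacement; a pyramid would matter for much larger frames
  and radii. This is a known limitation.
* **Oracle**: `flow_exact_map()` computes the exact minimum by junction
  -tree dynamic programming over image rows, exponential in the row
  width (width ≤ 4). The tests hold BP to within 1% of these exact minima
  on narrow textured instances.

The vessel-footprint polygon supplied to `velocity_map_series()` only
zeroes the reported fields outside the vessel; it plays no role in the
optimization. `line_velocity_from_field()` takes the maximum flow
magnitude along a line ROI (signed by the projection onto the line
tangent) as the RBC velocity — cells move faster than the plasma between
them, so the line maximum tracks cells. In texture-poor regions the
smoothness prior propagates labels from textured regions; dense cellular
texture (high hematocrit, as in real multifile vessels) is what anchors
the map, and the simulated mapping tests use dense-cell vessels for that
reason.

## Diameter and radial profiles

`measure_diameter()` samples the time-averaged image along a crossing
line, up-samples the profile 10× (cubic spline), differentiates, and
takes the two opposite-sign derivative extrema as the vessel edges; the
diameter is their separation. It is invariant to intensity scaling and
offset, errors on flat or monotone profiles, and for a Gaussian band of
width σ returns 2σ (the inflection separation).

`radial_profile()` shifts the axis polyline perpendicular to itself by
each requested offset and runs PIV on the kymograph at that chord; the
profile is the per-offset time-mean velocity. `fit_blunted_parabola()`
fits

$$V(r) = V_{max}\left[1 - (1-\beta)\left|\frac{r-r_0}{R}\right|^{B}\right]$$

by bounded Levenberg–Marquardt over `(Vmax, B, β, r0)` with `R` held
fixed at the measured radius — freeing `R` is degenerate with `Vmax` for
blunt profiles. Starting values are `Vmax = max(profile)`, `B = 2`,
`β = 0.1`, and `r0 = 0.01R` (an exactly centred start can place a sample
on the profile apex where the derivative with respect to `B`
degenerates), with a multistart over `B ∈ {1, 2, 4}` and an unbounded
fallback (validated against the constraints afterwards) for the
boundary case where the optimum sits exactly at `β = 0`.

The bluntness statistic is the closed form
`Vmax/Vavg = (B+2)/(B+2β)`, in which `Vavg` is the area-weighted average
over the lumen cross-section,
`Vavg = ∫₀ᴿ V(r)·2πr dr / (πR²)` — the integral the closed form inverts,
verified numerically to 1e-6 in the tests. (The chordal average across a
diameter is a different quantity, `Vmax(B+β)/(B+1)`, and is *not* what
the bluntness formula describes.) `B = 2, β = 0` gives 2 (ideal
parabola); `β = 1` gives plug flow, ratio 1.

## Flux and transit half-times

`count_rbc_events()` smooths the trace with a Gaussian window (width 3
frames), inverts it, and detects peaks by topographic prominence with a
minimum separation. The defaults — prominence 3× the median absolute
deviation of the running-median-detrended trace, separation 3 frames —
replace the interactive per-dataset tuning such traces traditionally get;
both are overridable, and for dense high-flux traces a fixed depth-based
prominence is the better choice (the MAD inflates when dips dominate the
trace). Counting is invariant to intensity scaling and offsets.

`fit_half_time()` splits each dip at its minimum and fits each edge with
a negative-amplitude Gaussian against a local baseline (median of
flanking windows just outside the dip). The fitting window walks outward
from the minimum until the trace recovers to within 2% of the provisional
baseline — wide enough that the flanking baseline is tail-free, narrow
enough to exclude neighbouring dips. The per-edge half-time is the
10%-to-90% crossing interval of the fitted Gaussian,
`σ·(√(2 ln 10) − √(2 ln(10/9))) ≈ 1.687σ`, and the event half-time
averages the two edges. Truncated edges are skipped with a warning.
`velocity_from_half_time()` converts to speed as `L / t_half` with
`L = 6 µm` (the RBC diameter); µm/ms is mm/s directly.

`bifurcation_flux()` space-sums each branch's cross-section image into a
1D trace and counts as above; on clean, well-separated events parent and
daughter-sum fluxes agree within 2%. `multifile_line_flux()` bins a
megahertz line-scan image in time until cells are roughly round, then
detects order-statistic local maxima (strict neighbourhood maximum above
a depth threshold). Side-by-side cells can merge into one blob, so the
count is a lower bound of the vessel flux; under-binning fragments blobs
and inflates the count, which the tests probe as a monotonicity check.

## Pulsatility

`velocity_spectrum()` resamples the trace onto a uniform grid (reporting
the interpolated fraction), removes the mean, optionally detrends,
applies a Hann window by default (the windowing convention is a package
choice), and normalizes the one-sided amplitude spectrum so that the
squared amplitudes sum to the (window-weighted) signal variance — with
the rectangular window this is the plain Parseval identity, asserted to
1e-6 in the tests. The cardiac fundamental is the largest peak in a
configurable search band, default 5–15 Hz for awake mice; harmonic order
k is declared present when the amplitude near `k·f0` exceeds 3× the
median floor of a surrounding neighbourhood, with the band width reported
at half prominence. Amplitude (not power) spectra are reported.

`pulsatility_index()` band-passes around `f0` (zero-phase FFT mask),
segments cycles at successive band-passed peaks, and averages
`(V_peak − V_min)/V_mean` over complete cycles: exactly `2m` for
`v₀(1 + m sin 2πf₀t)`, zero for steady flow, invariant to rescaling.
Trough-based segmentation would differ only in cycle phase, not in the
index, for the traces considered here.

`correlation_matrix()` resamples traces to the coarsest common grid and
computes Pearson correlations of the mean-removed fluctuations;
zero-variance traces get `NA` entries.

## Pipeline and reproducibility

`run_pipeline()` executes a YAML-declared stage list (simulation,
normalization, binning, PIV, spectra, pulsatility, event counting) with a
single seed, writes each stage's artifacts, and md5-hashes every output
into a manifest; a rerun with the same config reproduces the hashes
byte-for-byte. Unknown configuration keys are rejected by name. Because a
YAML file cannot carry an R function, the simulation stage accepts scalar
velocity-law parameters (mean, modulation depth, fundamental frequency)
instead of a `velocity_fn`.

TIFF output uses 32-bit samples scaled by an exact power of two
(recorded, with the calibration metadata, in a YAML sidecar next to the
image); the writer quantizes to 32 bits, so round trips are exact to
about 1e-9 of full scale. CSV round trips are exact.

## Problem sizes and test design

The test and acceptance suites size their simulations for completeness of
coverage at desk scale: kymographs of 0.05–2 s at 1–100 kHz line rates,
vessel videos of 20×48 to 40×120 px over 12–500 frames, flux records of
1–20 s at 1–5 kHz, SIFT-flow oracle instances of width ≤ 3 (where the
exact junction-tree minimum is computable) and mapping fixtures of
20×48 px with ~40 frames. Fit-recovery studies use 100 replicates at 5%
multiplicative noise. These sizes were chosen once, as representative
smallest-sufficient experiments for each claim; thresholds in the tests
come from the method contracts, not from observed outcomes.

## Known limitations

* Flow fields are integer-valued on the up-sampled grid: with the default
  2× up-sampling, velocity maps quantize at half a pixel per frame.
  Time-averaging across pulsatile modulation smooths this in practice.
* The wall bias of chordal radial profiles (finite cell size) described
  above.
* Belief propagation may oscillate on loopy graphs; the result is then
  the best labelling encountered plus the ICM polish, flagged by
  `converged = FALSE`.
* Only rigid, whole-frame motion correction; no intra-frame correction.
* The multifile flux count is a lower bound; no hematocrit estimation or
  cell classification is attempted.
* `faced_geometry()` encodes the closed-form virtual-source arithmetic
  for the printed mirror configurations; it does not model the optics
  beyond that arithmetic.
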