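---
title: "Methods: decomposing and synthesizing point-light biological motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing and synthesizing point-light biological motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(biomotion)
```

This vignette records the scientific model behind each stage of the
package, the assumptions it rests on, and the numerical and design choices
made where the underlying method leaves them open.

## From a contour to six point-light dots

A point-light stimulus reduces a fish to six dots p1..p6 placed along the
body at nearly regular intervals. The placement is posed as an
optimization over fourteen control points on the contour — `c0` at the
head tip, flank pairs `c1a/c1b` .. `c6a/c6b`, and `c7` at the tail tip —
parameterized by arc length. Each dot is the midpoint of a facing flank
pair, and the chain c0, p1, ..., p6, c7 has seven link lengths
L1..L7. The objective is

$$\mathrm{fitness} = \frac{\sum_i L_i}{\sqrt{\,n\sum_i X_i^2 - \left(\sum_i X_i\right)^2}},
\qquad X = (2L_1, L_2, \dots, L_6, 2L_7),\; n = 7 ,$$

i.e. the total chain length divided by (7 times) the population standard
deviation of the *effective* lengths X. The end links enter doubled
because c0 and c7 are body *tips* while the dots are body-interior
midpoints: at the optimum each end link is half an interior link, so the
six dots end up evenly spaced with half-spacing overhangs at the tips.
The discriminant under the root is the variance form `n ΣX² − (ΣX)²`,
which is zero exactly at equality of the effective lengths and positive
otherwise; the ratio is invariant to uniform rescaling of the contour.
Numerically, a discriminant at or below `1e-12` mm² returns the finite cap
`FITNESS_MAX = 1e9` rather than infinity so that hill-climbing comparisons
remain totally ordered without floating-point overflow.

**Optimizer.** The fitness is maximized by 1000 iterations of random-shift
hill climbing: one of the fourteen points is chosen uniformly at random,
its arc position is shifted by a step drawn uniformly from ±1% of the
perimeter, and the move is kept iff the fitness does not decrease. The 1%
step is a design choice: large enough to escape the even-spacing
initialization's basin within 1000 iterations, small enough to settle to a
link-length coefficient of variation well below 0.05 (the test suite
verifies CV < 0.05 on synthetic fish contours, and that the climbed fitness
reaches at least half of a coarse-grid brute-force optimum over the
even-spacing family). Whether the original procedure moved one point or
all fourteen per iteration, and whether downhill moves were ever accepted,
is not specified anywhere we could rely on; single-point greedy ascent is
our reading and is stated here as such.

**Head identification and temporal coherence.** Nothing in the method
defines which contour end is the head. For the first frame we take the
extreme of the major principal axis on the *wider* body end (fish are
head-heavy); later frames warm-start from the previous frame's arc
positions rescaled to the new perimeter, and the dot labelling is flipped
whenever the reversed order brings p1 closer to the previous p1. Warm
starting also means far fewer iterations are needed per subsequent frame;
`track_sequence()` exposes `warm_iterations` separately.

## Decomposition into posture and trajectory

The centre of mass is the area centroid of the contour (shoelace formula);
when only dots are available (synthetic dot-only pipelines), the arithmetic
mean of the six dots is the documented fallback. The travel angle is the
direction of the p6→p1 vector of the *same* frame — no temporal smoothing
is applied, since none is specified; a frame with p1 = p6 carries the
previous angle. The posture element is the dots translated by minus the
centre of mass and rotated by minus the travel angle (head on the +x
side); the trajectory element is the centre-of-mass path plus the angle
series. Recomposition inverts the two steps, and the roundtrip is exact to
floating point (tested at 1e-9 mm). Angles follow the mathematical
convention: counter-clockwise positive, zero along +x.

## The 2×2 stimulus family

Four clips cross the two factors. The non-biological trajectory moves at
exactly the biological mean speed (per-frame step `speed/fps`), and on
contact with the 10 mm margin of the 150×150 mm screen region a new
heading is drawn uniformly among directions pointing at least 20° into the
interior. "Random turn angle" fixes no distribution; the 20° grazing
exclusion prevents the path from sliding indefinitely along a wall, which
a bare uniform draw permits. The non-biological posture is six dots fixed
on the centre line at regular intervals, spaced by the source sequence's
mean consecutive-dot spacing so the stimulus extent matches the fish, and
oriented along the instantaneous travel angle for both trajectory types
(the centre line is tied to the traveling direction). Clips loop
back-to-back with no interstimulus gap; a 1-min clip at 30 fps contributes
1800 frames per loop.

## Quantifying attraction

The distance coordinate y (toward the display, smaller = closer) is
summarized three ways:

* **Minute means + Welch/BH.** Per-fish means over minute windows; the
  window just after onset is compared with the window before onset by a
  two-sample Welch t-test across fish, and p-values for the four stimuli
  are corrected by Benjamini–Hochberg at FDR 0.1. The two-sample (rather
  than paired) reading is a documented choice; the fractional degrees of
  freedom produced by Welch–Satterthwaite are consistent with it.
* **z-test.** A 1-s group-mean distance is referred to the baseline
  Normal(μ_y, σ) with a lower-tail probability; with μ_y = 41 mm and
  σ = 8.5 mm, a value of 24 mm gives P = 0.023 (z = −2.0).
* **Relaxation fit.** The group-mean series at 1-s resolution is fitted on
  t ≥ t0 by the one-parameter curve
  y(t) = (y0 − y_eq)·exp(−k(t − t0)) + y_eq. This orientation satisfies
  y(t0) = y0 and y(∞) = y_eq, i.e. it honours the stated meanings of the
  constants (y0 the most-attracted distance at t0, y_eq the pre-stimulus
  equilibrium); the algebraically different printed variant
  (y0 − y_eq)[1 − exp(·)] + y_eq evaluates to y_eq at t0 and is not
  boundary-consistent, so the package and its simulator both use the
  former. t0, y0 and y_eq are supplied, not estimated, mirroring their use
  as constants shared across all four stimulus fits.

**Uncertainty of k.** The rate is found by 1-D golden-section/parabolic
minimization of the residual sum of squares on [0, k_max] (tolerance
1e-10; a noiseless curve is recovered to ~1e-11). The standard error uses
the nonlinear-LS linearization σ̂/√Σg², g = ∂ŷ/∂k, inflated by the AR(1)
equivalent-sample-size factor √((1+ρ̂)/(1−ρ̂)) with ρ̂ the lag-1 residual
autocorrelation (clamped to [0, 0.9]): behavioural series remain serially
correlated after binning and averaging across fish, and the uncorrected
iid error is anticonservative. The interval on the retention time 1/k is
the delta method, with an optional Bonferroni-corrected level
(`bonferroni_m = 6` for the 4C2 pairwise comparisons of four stimuli). A
fit driven to k below 1e-4 /s (retention beyond ~3 h, unresolvable within
a session) is flagged `unbounded` and reports infinite retention. Under
the simulated study design (16 fish, 30 fps, 6-min session, k = 0.02/s,
AR(1) noise σ = 3 mm, φ = 0.9) the acceptance suite measures |bias| < 10%
of k and ≥ 90/100 CI coverage over 100 replicate simulations.

## Stimulus characterization

**Relative similarity.** 1 − d_B/(d_B + d_N) with d the flat Euclidean
norms of the stacked (frames × dots × coordinates) difference from the
biomotion and non-bio references, computed on positions relative to the
six-dot centroid *without* rotating away the travel direction. Any
monotone variant of the distance preserves the ordering but not the
boundary values 1 and 0, so the stacked norm is fixed. The degenerate case
d_B + d_N = 0 (all three series identical) returns 0.5 by symmetry.

**PSD slope.** Per-dot speed of the relative position is analysed by a
raw one-sided periodogram (no taper, DC excluded, `fast = FALSE` so the
series length is respected). Each dot's spectrum is normalized by its own
mean PSD (making the slope invariant to uniform rescaling), averaged
within logarithmic frequency bins (4 per decade) as the *logarithmic
mean* — the mean of log10, whose chi-squared sampling bias is the same
constant in every bin regardless of occupancy and therefore cancels in the
slope, unlike the log of the arithmetic bin mean, which tilts sparse
low-frequency bins — and pooled across dots into one linear regression of
log10 power on log10 frequency. The reported p-value is the Pearson
correlation test of the pooled points. Dots with no motion are flagged and
dropped; a fully motionless clip has an undefined slope.

**Classifier probe.** A single-hidden-layer feed-forward network (10
logistic hidden units, logistic output, cross-entropy loss) is trained on
flattened x–z dot series over 60-s windows (1800 frames × 6 dots × 2
coordinates = 21600 inputs) whose starting frames are drawn uniformly with
the time axis treated as circular, 100 windows per training clip, targets
1 for biomotion and 0 for non-bio. Training uses full-batch iRprop−
(sign-based step adaptation, steps in [1e-6, 1], 200 iterations): with
~2.2e5 weights an optimizer with a quadratic working matrix is not
practical, while Rprop is deterministic given the seed, insensitive to
input scaling, and linear in memory. Inputs are standardized by the global
training mean and SD. The probe is a reference indicator of what a simple,
near-linear recognizer can separate — nothing about it models the fish's
nervous system. Because the trajectory element dominates the coordinate
scale, the trained probe scores bio-trajectory clips like biomotion and
bio-posture clips like non-bio (verified over 5 seeds in the acceptance
suite), which is exactly the dissociation the similarity score explains.

## Synthetic data: what it emulates and what it does not

`generate_fish_contours()` builds a 2-D articulated fish: a teardrop
half-width profile (maximum width 20% of a 30 mm body) around a straight
body axis, a curvature wave traveling head→tail (default 2.5 Hz, 3 mm peak
amplitude, power-law amplitude modulation), a bounded random-walk heading,
and a speed series with a 1/f spectrum around 30 mm/s, reflecting at the
walls of a 150 mm arena. The polygon centroid is pinned exactly onto the
programmed path, so the path is usable ground truth for trajectory
extraction. These undulation parameters are plausible for a small
cyprinodontiform swimmer but are *free choices*, not measured medaka
values; no published posture spectrum constrains them. The generator makes
no attempt at hydrodynamics, 3-D pose, fin motion, or image-level realism,
so passing tests demonstrate correctness of the pipeline's geometry and
statistics, not fidelity to any particular animal.

`generate_powerlaw_signal()` shapes a white complex-Gaussian spectrum by
f^(β/2), truncates the envelope at the fundamental (DC set to zero — the
standard way to avoid low-frequency divergence for β < 0), inverse
transforms, and standardizes to the requested SD.

`generate_behavior_tracks()` realizes the relaxation model plus
stationary AR(1) noise on y (innovation SD scaled by √(1−φ²)); x is an
independent reflected random walk, and both coordinates are folded into
the arena by reflection. Noise is applied to y only because only y enters
the attraction analysis. The step from y_eq to y0 happens at t0 exactly;
the brief pre-t0 approach transient of a real session is not modelled, and
the fit never uses the pre-t0 window.

Every generator draws all randomness under a single integer seed and
restores the caller's RNG state, so identical seeds give bit-identical
output and test results are reproducible.

## Problem sizes

The test and acceptance runs use sizes chosen to exercise each property at
the scale where it is informative while keeping the suite quick to run:
100 random clips for the roundtrip identity; 20 fish contours (1000
hill-climb iterations each, grid oracle at 36 endpoint positions) for
optimizer quality; 100 replicate 16-fish sessions for rate recovery; 20
seeds of n = 8192 for spectral recovery; one 60-s tracked fish and 5 probe
seeds (100 windows of 1800 frames each) for the classifier pattern.

## Known limitations

* The six-dot conversion assumes a single, simple (non-self-intersecting)
  contour per frame; multi-fish scenes and occlusions are out of scope.
* The hill climb is greedy; on contours with long flat fitness plateaus
  (exactly equal effective lengths, where the cap applies) accepted
  equal-fitness moves can drift along the plateau.
* The relaxation model is intentionally minimal — one shared curve shape,
  one free parameter; it summarizes, rather than models, the approach
  dynamics, and per-fish heterogeneity enters only through the group mean.
* The PSD slope depends mildly on the binning resolution
  (`bins_per_decade`) for short series; the default of 4 is exposed.
* The probe's verdict depends on the coordinate scale of its inputs by
  design; it should never be read as evidence about what the animal can or
  cannot perceive.
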