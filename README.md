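# biomotion

Point-light biological-motion stimuli for fish behavioural assays:
decomposition, synthesis, and quantitative analysis.

Small fish such as medaka shoal with conspecifics, and they will approach a
display showing nothing more than a handful of moving dots if those dots
move the way a fish moves. But "moving the way a fish moves" conflates two
things: the **posture element** (body-shape-level motion — how the dots move
relative to the animal's centre of mass, expressed in a coordinate frame
rotated so the travel direction is horizontal) and the **motion-trajectory
element** (entire-field motion — the path of the centre of mass through the
arena). This package implements the full workflow for separating the two
and asking which one carries the attraction:

1. **Contour → six dots.** A tracked fish contour is converted into six
   point-light dots p1..p6 at nearly regular intervals. Fourteen control
   points (c0, c1a..c6a, c7, c6b..c1b) sit on the contour; each dot is the
   midpoint of a facing flank pair, and the seven links of the chain
   c0, p1, ..., p6, c7 are driven toward equal effective length by
   maximizing

   fitness = ΣL<sub>i</sub> / sqrt( n ΣX<sub>i</sub>² − (ΣX<sub>i</sub>)² ),
   X = (2L₁, L₂, …, L₆, 2L₇), n = 7,

   with 1000 iterations of random-shift hill climbing on the arc-length
   positions (a random control point is shifted by a random signed step and
   the move is kept iff the fitness does not decrease).
2. **Decomposition.** The centre of mass (polygon centroid of the contour)
   and the travel angle (direction of the p6→p1 line) define a rotated body
   frame; the dots' motion inside that frame is the posture element, the
   centre-of-mass path is the trajectory element, and the two recompose
   exactly.
3. **The 2×2 stimulus family.** Crossing biological/non-biological posture
   with biological/non-biological trajectory gives four clips: *biomotion*,
   *bio-posture*, *bio-trajectory*, *non-bio*. The non-biological trajectory
   is linear motion at the biological mean speed with random turns at the
   screen edges; the non-biological posture is six dots fixed on the centre
   line at regular intervals.
4. **Attraction analysis.** Minute-mean approach distances are compared by
   Welch's t-test with Benjamini–Hochberg FDR control; transient approaches
   are scored by a one-sided z-test against the baseline Normal(μ_y, σ);
   and the decay of attraction is summarized by a single-parameter
   exponential relaxation y(t) = (y₀ − y_eq)·exp(−k(t − t₀)) + y_eq whose
   inverse rate 1/k is the **retention time** of the attraction.
5. **Stimulus characterization.** Relative similarity
   1 − d_B/(d_B + d_N) between clips; the power-spectral-density slope of
   per-dot speed (biological clips follow a power law, the non-bio clip
   does not); and a single-hidden-layer classifier probe (10 units, 60-s
   windows, circular time axis) that shows what a near-linear recognizer
   can and cannot separate.

Synthetic-data generators (an articulated undulating fish contour in a
150 mm arena, power-law signals, and behavioural response tracks with known
relaxation kinetics and AR(1) noise) make every stage testable end to end
without any recordings.

## Worked example

```r
library(biomotion)

# synthesize a swimming fish and track it into six dots
contours <- generate_fish_contours(duration = 10, seed = 1)
dots <- track_sequence(contours, iterations = 1000, warm_iterations = 60,
                       seed = 2)
dots
#> <dot_sequence> 300 frames x 6 dots at 30 fps

# the 2x2 stimulus family
stim <- make_stimulus_set(dots, seed = 3)
stim$biomotion
#> <stimulus_clip> biomotion: 300 frames (10 s x 1 loops) at 30 fps

# body-shape-level similarity of the bio-posture clip to the two references
relative_similarity(relative_position_series(stim$`bio-posture`),
                    relative_position_series(stim$biomotion),
                    relative_position_series(stim$`non-bio`))
#> relative similarity 0.0789 (d_B = 439, d_N = 37.7)
```

The bio-posture clip scores 0.08 — far closer to the non-bio reference than
to biomotion — because without rotating away the travel direction the
trajectory difference dominates the Euclidean distance, even though the
clip's body-frame posture is fully biological.

```r
# simulate 16 responding fish and fit the relaxation
tracks <- generate_behavior_tracks(k_true = 0.02, noise_sd = 3,
                                   ar1_coeff = 0.9, n_fish = 16, seed = 4)
ys <- mean_y_series(tracks)                 # group mean at 1-s resolution
fit <- fit_relaxation(ys$t, ys$y, t0 = 77, y0 = 10, y_eq = 41,
                      bonferroni_m = 6)
summary(fit)
#> Exponential relaxation fit
#>   constants: t0 = 77 s, y0 = 10 mm, y_eq = 41 mm
#>   k = 0.02002 1/s (SE 0.000114); retention 1/k = 49.9 s
#>   95% CI (Bonferroni m = 6) on k: [0.01972, 0.02032] 1/s
#>   95% CI (Bonferroni m = 6) on 1/k: [49.2, 50.7] s
#>   residual SD 0.485 mm over 283 points

# transient approach to 24 mm against baseline Normal(41, 8.5)
signif(ztest_attraction(24, mu_y = 41, sigma = 8.5), 2)
#> [1] 0.023
```

The fitted rate recovers the simulated ground truth (k = 0.02/s, retention
50 s), and the z-test says a 1-s mean distance of 24 mm would occur with
probability 0.023 under the no-stimulus baseline.

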