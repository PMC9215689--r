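---
title: "Shape comparison, simulated observers and touch baselines: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape comparison, simulated observers and touch baselines: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`shapeback` is a workbench for one-back same–different shape comparison
experiments of the kind used to ask whether vision and touch evaluate shape
with the same features. A participant (or here, a simulated observer) sees or
feels a stream of abstract 2D silhouettes and reports after each one whether
it is the same shape as the previous one, ignoring rotation. The package
covers the full analysis loop:

1. **Stimuli** — random "blob-union" silhouettes, canonicalized to ordered
   perimeter point lists at 0.1 mm spacing and scaled to 25 mm maximum
   extent (the physical size of the extruded haptic objects such tasks use).
2. **Dissimilarity metrics** — eight shape measures, three of which come in
   a presented-orientation (`@actual`) and a rotation-optimized (`@optimal`)
   variant, eleven predictor columns in all.
3. **Sessions and observers** — the 8-block, 72-trial one-back design, and a
   logistic choice model with lapse that turns metric values into simulated
   responses.
4. **Model selection** — per-metric binomial GLMs compared by AIC against a
   stored uniform-random baseline, with a forward stepwise multimetric rule.
5. **Touch analysis** — a Monte Carlo baseline for how often each of six
   perimeter touchpads would be contacted by chance, against which observed
   (or simulated) touch dwell is compared as a function of local curvature.

## Stimulus generation

Each shape is the union of 2 or 3 blobs. A blob is a periodic (closed) cubic
spline through 3 control points drawn uniformly in the unit disc,
parameterized by cumulative chord length; self-intersecting splines are
rejected and redrawn. Blob centers are offset uniformly within a disc of
radius 0.5 so overlap is probable; a union whose blobs do not form a single
connected region is rejected and resampled, as is any union whose outer
boundary fails a brute-force simplicity check. Interior holes (possible with
three blobs) are dropped — the stimuli are filled silhouettes. The outer
boundary is scaled so the maximum axis-aligned extent is exactly 25 mm and
resampled to N = round(perimeter / 0.1 mm) points at uniform arc spacing
(so there is no short closing segment; typical shapes have 600–800 points).
Perimeters are stored counterclockwise, starting at the minimal-(y, x)
vertex, which makes turning functions and curvature signs deterministic.
Because corner-cutting during resampling shrinks the extent by
O(spacing²/R), a final uniform rescale restores the 25 mm extent exactly.

Where the construction is under-specified by its sources, the choices above
(spline family, control-point distribution, rotation about the area
centroid, equal-arc resampling) were made once, for standardness and
determinism, and are exercised by the test suite rather than revisited.

## The metrics

For shapes A (previous trial) and B (current trial), all presented at their
trial orientations:

* **Curvature distribution** — at every perimeter point p, the angle between
  the chords from p to p−50 and p to p+50 (span 101 points ≈ 5 mm half-span);
  straight stretches give 180°, convexities less, concavities more. The
  dissimilarity is the sum squared difference of the two empirical CDFs on a
  fixed 0–360° grid in 0.5° steps. Rotation invariant. In the continuum limit
  a circle of radius r gives exactly 180° − (180/π)(5.0/r); at 0.1 mm
  sampling the realized half-span arc is 50·P/N ≈ 5.0 mm, which moves the
  value by up to ~0.02° — the tests assert at that discretization tolerance.
* **Aspect ratio** — bounding-box xspan/yspan maximized over 360 rotations at
  1° steps (`@optimal`, orientation invariant, ≥ 1). The `@actual` variant
  finds the absolute frame angle at which the *previous* shape (as presented)
  attains its maximum and measures the current shape's ratio at that same
  frame angle — the "no mental rotation" assumption. Dissimilarity is the
  squared ratio difference.
* **Area, convex hull area, compactness** — shoelace area, hull-of-points
  area, and their quotient (1 for convex shapes); squared differences.
* **Turning distance** — each outline's cumulative counterclockwise tangent
  angle as a piecewise-constant function of normalized arc length (total
  turning +360°; size and translation invariant). Both functions are
  evaluated on a common uniform grid (default 1024 samples) and the L2
  distance is minimized over all circular start shifts, with the constant
  angular offset optimized in closed form at each shift. The shift search is
  computed exactly via a circular cross-correlation of ψ(s) = θ(s) − 360s,
  which is 1-periodic; the tests verify it against a literal double loop.
* **Intersection over union** and **Hausdorff distance** — after aligning
  area centroids ("centerpoints" is read as area centroid: robust to
  protrusions, flagged as an open interpretation), IoU is overlap area over
  union area and the Hausdorff distance is the largest nearest-point
  distance between the perimeter point sets, both symmetric. `@actual`
  evaluates at the presented orientations; `@optimal` searches rotations of
  the current shape on a `rotation_step_deg` grid (default 1°, mirroring the
  stated aspect-ratio granularity; the true search step of the original
  analyses is unstated). The grid always contains the presented relative
  orientation, so IoU@optimal ≥ IoU@actual and Hausdorff@optimal ≤
  Hausdorff@actual hold *exactly*, not just statistically.

Polygon overlap is computed by an O(nm) boundary-integration routine in C++
(sub-segments of each boundary inside the other polygon, integrated with the
shoelace kernel); IoU polygons are downsampled to `iou_points` (default 256)
perimeter points, which biases a 25 mm shape's IoU by ~1e-4 while making the
1° optimal search affordable. Hausdorff uses the full outline by default
with an early-break scan. Exactly coincident point sets (match trials at 0°
rotation change) shortcut to IoU = 1 / Hausdorff = 0 before the general
routine, whose boundary-integration is undefined for exactly coincident
edges.

## Sessions and the synthetic observer

A block holds 72 trials over exactly 48 unique shapes with 24 match trials;
match-trial orientation changes are 0°/±90°/180° in an 8:8:8 split with the
90° class split randomly between +90 and −90. A session is 2 visual-only, 2
haptic-only and 4 alternating blocks in permuted order. Each block's first
trial has no referent: it is labeled `warmup`, excluded from every fit, but
counted under the block's nominal condition so the design tally is exactly
144 trials per condition (VV, HH, VH, HV) — matching the bookkeeping that
reports 72 × 8 trials as 4 × 144.

The observer responds "different" with probability
(1 − ε)·logistic(β0 + Σ βk·dk) + ε/2, where dk are dissimilarity columns,
ε is a lapse rate entering as uniform guessing (the standard psychophysics
form; the source analyses fit real humans and state no observer model), and
the metric variant can be resolved per condition to emulate
within-modal/cross-modal differences in mental rotation. Weights may be
applied to raw or z-scored columns; raw columns keep the convenient property
that match trials (dissimilarity exactly 0) see p("different") =
logistic(β0), while z-scoring makes one weight magnitude comparable across
metrics whose raw scales differ by orders of magnitude. The random baseline
`random_u` is drawn once per trial and stored in the table, so every model
comparison sees the same realization under a session seed.

## Metric evaluation

Every metric column is standardized and fit alone as a binomial GLM
(logistic, IRLS, convergence 1e-8) predicting the "different" response; the
AIC is 2k − 2lnL with k = 1 + #predictors. A metric is *predictive* when it
beats the stored random baseline by ≥ 3 AIC units. Multimetric selection is
forward stepwise from the best single metric, adding the largest AIC
improvement and stopping when no candidate improves by ≥ 3 — the
fewest-variables rule. Complete separation (possible with near-deterministic
simulated observers) is flagged via `converged = FALSE`, not penalized away.
Evaluation pools trials by default (`condition = "all"`) or filters to one
condition; whether the original analyses pooled participants is unstated, so
pooling is the package default and a per-condition option is the interface.

The dissimilarity–accuracy curve bins nonmatch trials into equal-count bins
(default 10; the source binning is unstated) and correlates bin-mean metric
value with the proportion of correct "different" responses.

Behavioral summaries report percent correct, hit rate ("same" on a match
trial), false-alarm rate, d′ = z(hit) − z(FA) with the 1/(2N) correction for
extreme rates, and median RT when present.

## Touch baseline and curvature enrichment

Each perimeter is divided into six contiguous equal-arc-length touchpads
from the canonical start point (how the physical foil tape was sectioned is
unstated; equal arc length is the reproducible choice). The Monte Carlo
baseline samples 100,000 points uniformly in the bounding box padded by the
6 mm finger radius; a point is a touch iff it lies outside the polygon at a
perimeter distance within [4 mm, 6 mm] (rigid core vs finger radius), and
every pad partly within 6 mm of the point is credited; credit vectors are
normalized to ratios.

Pad curvature is scored as the mean absolute deviation of the span-101 local
angle from 180° over the pad's points (the source plots "curvature" per pad
without defining it). Enrichment is observed ratio / baseline ratio, with
observed ratios dwell-time weighted by default (count weighting available),
and the headline statistic is the Pearson correlation between pad curvature
and enrichment across all pads of all shapes. **Sign convention**: positive r
means curved pads are touched more than chance predicts. (The source
reports the within-haptic correlation as +0.32 in its text and −0.32 in a
figure caption; this package documents its convention rather than guessing
which sign was a typo — the verbal description, "more curvature, touched
more", corresponds to positive r here.)

The simulated toucher visits pads with probability proportional to
baseline·(1 + γ·n(curvature)), where n() centers the six pad scores and
scales them into (−0.455, 0.455) (largest absolute deviation divided by
2.2): with this bounding every gain γ ∈ [−2.2, 2.2] yields a valid
probability vector, covering the gains the tests exercise (−0.5, 0, 2),
while γ beyond that range fails loudly. Visits per trial are Poisson with
mean 12 (matching observed per-trial pad-touch counts near 12); dwell times
are log-normal (median 300 ms, σ = 0.5 log-units) — plausible magnitudes for
exploratory touch, used only as weights.

## What the generator does and does not emulate

A green metric-recovery test establishes that the analysis pipeline
identifies the metric an observer actually used, on sessions whose design
exactly matches the task (trial counts, match ratios, orientation classes)
and whose choice noise is binomial with lapse. It does *not* establish
anything about serial dependencies, learning, RT–accuracy coupling, memory
decay over the one-back interval, or saccade/finger kinematics — none of
which the generator models. The stimulus generator reproduces the
construction recipe, not the 48 original stimuli (their seeds were never
published), so per-shape metric values are statistically, not numerically,
comparable.

## Numerical choices and scaled-down test settings

* Rotation searches default to 1°; the dominance invariants hold for any
  step because the presented offset is always in the search set.
* The bulk simulation tests (metric recovery over 10 seeds, touch-bias sign
  recovery) run with a 15° search, 96-point overlap polygons and 20,000
  Monte Carlo samples to fit a CI budget; these properties are
  granularity-invariant, and the analytic and oracle tests run at the
  defaults.
* Degenerate inputs fail loudly: zero-area polygons, clockwise outlines
  (auto-reoriented with a warning in `turning_function`), constant GLM
  predictors, pads with zero baseline (excluded with a warning), gains
  outside the admissible range.
* All randomness flows through per-stage seeds derived from one global seed;
  two runs with the same configuration produce byte-identical artifacts
  (hashed in the run manifest).

## Known limitations

* Polygon booleans assume general position; exactly coincident non-identical
  boundaries (zero-measure under the generator) are not handled beyond the
  identical-shape shortcut.
* The @actual aspect-ratio frame search is on the same 1° grid as the
  @optimal maximization; sub-degree frame angles are not interpolated.
* The Monte Carlo sampling region is the padded bounding box; geometries
  whose touch annulus extends beyond it (impossible here) would be clipped.
* The observer is memoryless and stationary; session-order and learning
  effects present in real data have no synthetic counterpart.
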