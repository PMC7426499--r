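---
title: "Methods: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysla)
```

This vignette documents the measurement models implemented in flysla,
the conventions adopted where the underlying assay leaves details open,
and what the synthetic-data validation does and does not establish.

## The single-arena SLA assay

One fly walks in a flat, back-lit circular chamber (20 mm diameter,
3 mm height) and is filmed from above. The analysis chain is:

1. **Detection.** In each frame the fly is the set of pixels strictly
   brighter than an intensity threshold (default 60 on the 8-bit
   scale). Its position is the weighted mean of those pixel
   coordinates. We use intensity weights by default, because the blob's
   brightness profile then yields a sub-pixel position estimate; a
   binary-mask centroid is available via `weighted = FALSE` in
   `detect_centroid()`. "Brighter than" is a strict inequality.
2. **Calibration.** `calibrate_from_arena()` takes the largest bright
   connected region of an arena image as the chamber disk, places the
   centre at its centroid, and derives the radius from its area, giving
   `mm_per_pixel = 20 / fitted diameter`. A manual calibration can be
   supplied instead. Trajectories are arena-centred, in mm, with +y up
   (the image row axis is negated).
3. **Missing frames.** Frames with no super-threshold pixel are flagged
   and excluded; they are never interpolated, because interpolation
   would invent motion. A quantum needs at least two detected samples to
   contribute; otherwise it is invalid and excluded from every
   parameter.

## Quantization and the rest/run dichotomy

The record is divided into quanta of 1 s. A quantum's mean speed is the
summed displacement between consecutive detected samples over that
second, divided by the quantum duration — path length, not net
displacement, since the quantity of interest is how much the fly moved,
not where it ended up.

Two conventions deserve explicit statement:

* **Quantum windows are closed intervals.** Quantum *k* covers
  [*k*−1, *k*] s and shares its boundary sample with its neighbour, so a
  full quantum at `f` frames/s contains exactly `f` steps. The
  alternative — binning samples half-open so each quantum holds only
  `f − 1` steps — systematically underestimates every speed by the
  factor (f−1)/f (10% at 10 frames/s) and would make the measured
  running speed of a calibrated walker irrecoverably biased below its
  generative value. The closed-window rule measures exactly the path
  traversed during the quantum's second.
* **The boundary speed classifies as run.** Rest is defined by mean
  speed *lower than* 1 mm/s; the complement, including exactly
  1.00 mm/s, is run.

Bouts are maximal blocks of consecutive valid run quanta. Bouts
truncated by the record edges (or interrupted by invalid quanta) are
counted: excluding them would bias mean bout time downward, most
strongly for the most active flies. With these definitions the identity

```
run_frequency * run_bout_time = 100 * index_of_activity
```

is algebraically exact whenever bouts exist (both sides equal
`100 * run quanta / valid quanta`), and the suite asserts it on every
simulated record. The index of activity is reported as a fraction in
[0, 1] — the natural reading of "conventional units" for a
time-fraction — with `activity_as_percent = TRUE` as a toggle.

The **centrophobia index** quantifies wall-following: the fraction of
detected samples farther from the centre than 0.7 × arena radius. The
0.7 cutoff is this package's convention (the behaviour is usually
reported qualitatively); under uniform-over-area exploration the
expected index is 1 − 0.7² = 0.51, so values well above 0.51 indicate
wall preference. The cutoff is exposed in `analysis_config()`.

## The synthetic walker

Real recordings have no ground truth, so validation rests on a
generative stand-in that realizes exactly the dichotomy the metrics
measure: a two-state (rest/run) Markov walker in the arena disk
(`walker_params()`, `simulate_walker()`).

* **State process.** Sojourns follow a discrete chain on the 1-s
  quantum grid with per-second switch probabilities
  `1 − exp(−rate)`. Aligning state changes with quantum boundaries is a
  deliberate design choice: it makes every quantum homogeneous in
  state, so the estimated index of activity and running speed are
  unbiased for their generative counterparts and recovery can be tested
  sharply (within Monte-Carlo error) rather than against an
  estimator-artefact bias. The stationary run fraction of this chain is
  `p1/(p1+p2)` with `p_i = 1 − exp(−rate_i)`; for equal rates it is
  exactly 1/2, and for small rates it approaches the continuous-time
  value `k1/(k1+k2)`.
* **Run kinematics.** Each run bout draws one speed from
  N(`run_speed_mean`, `run_speed_sd`), truncated below at 1 mm/s so
  every run bout classifies as run; within the bout each frame advances
  by `speed / frame_rate` with heading increments that are
  wrapped-normal with SD `1/sqrt(turning_concentration)`.
* **Rest kinematics.** Isotropic jitter with exponential per-frame step
  lengths of mean `rest_speed_mean / frame_rate` — sub-threshold by
  construction for `rest_speed_mean < 1`.
* **Walls.** When a step would exit the disk, the heading is reflected
  about the local tangent and blended toward the tangent with weight
  `wall_bias` (0 = specular reflection, 1 = full tangential alignment),
  and the full-length step is retaken; a rare fallback steps toward the
  centre. Retaking the full step preserves path length, hence the
  recoverability of running speed; the tangential bias reproduces
  qualitative wall-following, with `wall_bias = 1` walkers scoring
  clearly higher centrophobia than `wall_bias = 0` ones.
* **Defaults.** 10 frames/s (a typical webcam rate; the assay's camera
  rate is a free choice here), 3600 s records, switching rates 0.1/s
  (10-s mean sojourns), run speed 3 ± 0.5 mm/s, rest jitter 0.1 mm/s,
  wall bias 0.7, arena radius 10 mm. All are configurable; seeds make
  every generator byte-deterministic.

The **renderer** (`render_params()`, `render_frames()`) paints a
radially symmetric Gaussian blob (peak 200, σ = 2 px by default) on
normal background noise, rounded to 8-bit. Body shape and orientation
are not modelled — the tracker only consumes a centroid. The defaults
enforce `peak > 60 > background mean + 3 SD`, so the fly is detectable
and the background essentially never is.

What passing these tests shows — and does not show. The synthetic data
establish that the implementation measures its own generative model
correctly: sub-pixel tracking on rendered frames, unbiased recovery of
activity and speed, exact algebraic identities. They do not establish
robustness to real-world nuisances the generator omits: reflections and
shadows, the fly's elongated body and grooming micro-movements,
illumination drift, occlusion at the wall, codec artefacts. Threshold
and calibration should still be inspected per recording.

## Group statistics

`mann_whitney_u()` implements the two-tailed Mann–Whitney U test
directly (rank sums with midranks). For `n1 + n2 <= 20` without ties
the p-value is exact, by full enumeration of all `choose(n1+n2, n1)`
rank assignments; otherwise a normal approximation with tie correction
and, by default, a 0.5 continuity correction is used (the correction is
a flag, `continuity`). The two-tailed p is twice the smaller tail
probability, capped at 1. The suite checks the exact path against an
independent implementation, the complement identity
`U_a + U_b = n1*n2`, exact-vs-approximate agreement at n = 8 + 8, and
the empirical type-I error at the 5% level under a simulated null.

Comparisons follow the cross-sectional design of ageing cohorts:
between strains at matched ages, and each strain's older ages against
its own baseline age (default day 5). No multiplicity correction is
applied by default — each comparison is reported at its nominal p, as
is conventional for these tiered figures — but `p_adjust` accepts any
`stats::p.adjust` method. Significance tiers are 1/2/3 for
p < 0.05/0.01/0.001. Note the exact test's granularity: with n = 6 per
group the smallest achievable two-sided p is 2/924 ≈ 0.002, so tier 3
requires larger groups regardless of effect size.

## Densitometry

OD is operationalized on 8-bit images as
`max(0, background mean − spot mean)`, with the background taken from a
concentric annulus around each spot. A local annulus (rather than a
global background patch) makes OD invariant to adding a constant to the
image and robust to smooth illumination gradients; the floor at 0 keeps
OD a non-negative signal measure. Spot positions are supplied by the
user as circles — dot blots are gridded manually, and no automatic spot
finder is attempted.

Normalization schemes: division by a same-sample loading control
(β-actin or total protein), or division by the age-cohort mean
("conventional units"), which by construction gives every cohort mean
exactly 1. The standard curve is ordinary least squares of OD on
concentration with R² reported; inversion warns outside the fitted
range. The membrane phantom renders spot darkness exactly proportional
to concentration, so the noiseless fit must return R² = 1 and slope
equal to the generative darkness-per-unit — an exact oracle — while a
noisy series (background SD 2) must stay above R² = 0.99.

## Pedunculus ratio

For a square ROI *x* placed on the dimmed pedunculus and the same-size
ROI *y* placed immediately above it (toward the image top, adjacent and
non-overlapping; the offset is configurable via `y_offset`), the three
optical slices with the lowest ROI-*x* mean are selected (ties resolved
toward lower slice indices), *x* and *y* are averaged over those slices
first, and R = x̄/ȳ. Averaging before the ratio is the implemented
reading; per-slice ratios averaged afterwards are available via
`slice_average = "after_ratio"` (identical on noiseless phantoms, and
nearly so at realistic noise). R is exactly invariant under a global
intensity gain, and equals the phantom's `ped_contrast` on noiseless
stacks. When validating with phantoms, the geometry must keep the *x*
ROI inside the dimmed disk and the *y* ROI clear of it — an inscribed
8-px ROI with a 16-px upward offset for a radius-6 disk in the test
fixtures. Group comparisons of R use Welch's two-sided t-test by
default (variances are not assumed equal); the Mann–Whitney alternative
is a flag.

## Pipeline, determinism and problem sizes

`run_cohort()` drives simulate → quantize → profile → compare from one
flat config (R list, YAML or JSON), writing per-fly profiles, group
summaries, the comparison table, and a manifest with the seed, the
package version and an MD5 checksum of every output. Per-fly seeds are
derived deterministically from the run seed, so identical configs
reproduce byte-identical tables.

Validation problem sizes were chosen to make Monte-Carlo bands tight
while keeping the full suite quick to run on a laptop: hundreds of
30-s walkers for the algebraic identities, 100 two-second rendered
clips for tracker RMSE, twenty hour-long walkers for parameter
recovery, 1000 null replicate pairs (n = 20 each) for the type-I rate,
and 20 noisy phantoms for ratio recovery. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch
under a caller-supplied seed.

## Known limitations

* The tracker assumes exactly one bright object; multi-fly arenas,
  identity maintenance and body orientation are out of scope.
* Quantum speed from sparse detections (gaps inside a quantum) is a
  lower bound on path length, since the path between two detected
  samples is taken as a straight chord.
* The walker is a behavioural caricature: no biomechanics, no flight,
  no grooming; its purpose is metric validation, not fly simulation.
* Dot-blot quantification assumes approximately uniform spot interiors;
  saturated or ringed spots violate the linear OD model.
* The "C.U." activity scale and the 0.7 centrophobia cutoff are package
  conventions, stated here so results can be compared across labs.
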