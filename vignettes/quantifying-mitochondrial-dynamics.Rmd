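---
title: "Quantifying mitochondrial dynamics: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dynamics: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

mitoquant turns four microscopy readouts of mitochondrial dynamics into
numbers: per-object shape and per-cell network morphology from
fluorescence images, tethering-event kinetics from two-channel
time-lapses, ER–mitochondria contact-site geometry from traced outlines,
and matrix-mixing curves from photoactivation series. This vignette
explains the models behind each stage, the parameters that matter, what
the synthetic generators do and do not emulate, and where genuinely open
design choices were settled.

## Segmentation and the aspect ratio

A fluorescence image of mitochondria is reduced to labeled objects in
three steps. Background is removed by a morphological **white top-hat**
with a disc of radius `background_radius_px` (default 50 px): any
structure wider than the disc is treated as slowly varying background,
anything narrower — mitochondria-scale objects — passes through
unchanged. The top-hat is a deterministic stand-in for the rolling-ball
style background subtraction common in interactive tools, with the same
single radius parameter. The image is then thresholded (Otsu by default;
a fixed threshold is available when exact reproducibility across
preprocessing variants matters) and connected components are labeled at
8-connectivity (4-connectivity available), discarding objects below
`min_object_area_px` (default 4 px, suppressing single-pixel noise).

Each object's **aspect ratio** is the axis ratio of the ellipse sharing
the object's second central moments, the convention of standard
particle-analysis tools: if $\lambda_1 \ge \lambda_2$ are the
eigenvalues of the pixel covariance matrix, $AR = \sqrt{\lambda_1 /
\lambda_2}$. AR is 1 for a disc, equals the side ratio for a rectangle,
and is rotation invariant up to pixel discretization (within 2% for
objects of 200 px and larger — one of the package's property tests). The
implementation takes major axis and eccentricity from
`EBImage::computeFeatures.moment`, so tests can check it against an
independent brute-force moment oracle computed from raw pixel
coordinates. A minor axis shorter than one pixel (a zero-thickness pixel
row) is floored at 1 px to keep the ratio finite.

Coordinates are 1-based (row, column) throughout, R's native indexing;
CSV outputs use the same convention.

## Network-morphology classification

The four classical network categories are usually called by eye. Here
they are explicit functions of three per-cell statistics, evaluated in
priority order Collapsed → Hyperfused → Elongated → Fragmented, with an
Intermediate fallback (the four categories are not provably exhaustive
once the rules are explicit):

* an object is **tubular** when AR ≥ `tubular_ar_min` (default 2.0 —
  a deliberate operationalization; whether "tubular" should be length-,
  AR-, or curvature-based is not fixed by convention, and AR is the
  choice here, exposed in the configuration);
* **Elongated** / **Fragmented**: strictly more than `class_fraction`
  (default 0.9) of objects tubular, respectively round;
* **Hyperfused**: the largest connected component holds at least
  `hyperfused_component_fraction` (default 0.75) of total mitochondrial
  area *and* is reticular rather than blob-like, operationalized as
  circularity $4\pi A / P^2 \le$ `hyperfused_circularity_max` (default
  0.5; a disc scores ≈ 1, a thin tube of length $L$ and width $w$
  roughly $w/L \cdot \pi^{-1}$-scaled values well below 0.5);
* **Collapsed**: the fraction of mitochondrial area within
  `collapsed_radius_fraction` (default 0.15) of the **cell image
  diagonal** around the mitochondrial area centroid is at least
  `collapsed_area_fraction` (default 0.75). The clumping radius is
  anchored to the analyzed field (the cell fills the frame in single-cell
  crops) rather than to the foreground bounding box: a perinuclear clump
  shrinks its own bounding box, which would make a bbox-anchored radius
  self-defeating.

Priority order resolves cells satisfying several rules at once — a
clumped network is Collapsed even if it is also one big component. The
per-cell AR statistic reported alongside is the unweighted mean of
object ARs (per-cell aggregation is the default; averaging per field of
view is the same function applied to a field's object table). Condition
summaries report the percentage of cells per class with the SEM taken
across replicates, the replicate being the unit of error in triplicate
experiments; AR comparisons across conditions delegate to
`stats::aov` (one-way ANOVA).

## Tethering events

In a two-channel time-lapse (foci + mitochondria, fixed interval `dt_s`,
default 3 s), foci are detected per frame by matched-filter smoothing at
the spot scale, local-maximum extraction above `spot_threshold`, and
sub-pixel refinement by intensity-weighted centroid. Detections are
linked frame to frame by greedy nearest-neighbor assignment within
`max_link_px`, closing gaps up to `max_gap_frames` (default 1). The
greedy linker is sufficient for sparse, slowly moving foci; a full
cost-matrix assignment is deliberately out of scope, and the generators
produce scenes where greedy and optimal coincide (a property checked
against an exhaustive-assignment oracle on two-spot scenes).

A **tethering event** opens when a track's focus lies within
`adjacency_radius_px` (default 3 px) of two or more distinct
mitochondria — the operational form of "visibly tethered through a
focus" — and closes at the last frame where that holds. Duration is
`(end_frame − start_frame) × dt_s`, so a single-frame contact has
duration 0 and every duration is a multiple of the frame interval. Only
events **strictly longer** than `min_event_s` (default 15 s) are
reported; the strict inequality follows the "more than 15 s" phrasing of
the rule, so a 15.0 s event is excluded and an 18.0 s event kept. The
outcome is:

* **fused** — the two partner mitochondria map onto one and the same
  merged object for `fusion_confirm_frames` (default 2) frames after the
  event; the confirmation window keeps transient touching from being
  scored as fusion;
* **separated** — both partners persist as distinct objects;
* **censored** — the event reaches the end of the stack (or there is no
  room left to confirm). Censored events are excluded from mean-duration
  statistics, since their dwell time is a lower bound only; whether to
  include them is genuinely open, and exclusion is the conservative
  choice.

Partner identity across frames is maintained by pixel-overlap mapping
rather than label numbers, because connected-component labels are not
stable between frames. Dwell-time comparisons between two conditions
report the ratio of mean durations and a Welch t-test p-value
(`stats::t.test`).

## Contact-site geometry

Traced annotations come as closed mitochondrial polygons and open ER
polylines in physical nm. Each ER trace is resampled at uniform
arc-length steps (`step_nm`, default 5 nm); each sample gets the
Euclidean distance to the nearest mitochondrial boundary (0 inside a
polygon) and the projection of itself onto that boundary as a perimeter
arc coordinate. Maximal runs of consecutive samples with distance ≤
`max_gap_nm` (default 60 nm) and a constant nearest mitochondrion become
**contact sites**; a run is split when the nearest mitochondrion
changes, so each contact belongs to exactly one mitochondrion, matching
per-mitochondrion reporting. Contact length is the arc span of the run;
the **GAP** is the mean sampled distance over the run (the per-contact
reduction is not fixed by convention; mean is the default and minimum is
available as `gap_stat = "min"`). GAP bins are half-open-left — [0, 15),
[15, 30), [30, 60] — resolving the overlapping printed endpoints of the
conventional 0–15 / 15–30 / 30–60 ranges; a GAP of exactly 15 nm falls
in the middle bin.

Per-cell summaries report contacts per mitochondrion, mean contact
length, mean mitochondrial perimeter, and **percent perimeter
coverage**: projected sample positions of each contact are joined into
circular intervals on their mitochondrion's perimeter and the union
length (never the sum) is divided by total perimeter, so overlapping ER
traces cannot push coverage past 100%. Halving `step_nm` moves lengths
and coverage by well under 1% (a convergence test in the suite).

## The PA-GFP fusion assay

Matrix-targeted photoactivatable GFP reports content mixing: after
activating a small region, the GFP-positive area can only grow beyond
the activated zone by fusion with unlabeled mitochondria. The package
measures, at each timepoint (default 0, 5, 10 min), the number of pixels
inside the mitochondria mask whose intensity exceeds a threshold fixed
at t = 0 as `threshold_frac` (default 0.2) of the median activated
intensity in the photoactivation ROI — the operational definition of
"GFP-positive area", which imaging protocols leave unstated — and
normalizes to the t = 0 area, so the first value is exactly 1.
Restricting to the mitochondria mask excludes cytosolic background
(nearly a no-op for matrix-targeted probes). No photobleaching
correction is applied; the synthetic fixtures are bleach-free, and real
data with appreciable bleaching would need a correction upstream.
Per-condition curves are averaged pointwise with SEM across cells.

## The synthetic generators

Each generator renders a modality with programmed ground truth and is
bit-identical under identical spec + seed (`with_seed` isolates the RNG
so generation does not disturb the session).

* **Morphology images**: round blobs (discs) and curved tubules
  (constant-width tubes along quadratic Bézier paths with bounded
  curvature, so the moment-ellipse AR of a tubule stays within a few
  percent of the straight-tube value and ground truth remains
  computable). Objects are placed without overlap (capsule–capsule
  clearance wide enough that the PSF cannot bridge neighbors at
  threshold) and away from borders; hyperfused cells are one spanning
  reticulum (tubes along the minimum spanning tree of spread-out nodes —
  spread is enforced so a hyperfused mask never satisfies the Collapsed
  rule, keeping truth labels consistent with the classifier);
  collapsed cells pack objects into a disc of radius 0.15 × image width
  around the center, an operational stand-in for perinuclear clumping.
  The image model is object intensity 0.8, Gaussian PSF (σ 1 px),
  Poisson shot noise (scale 400) plus Gaussian read noise (σ 0.01) —
  defaults chosen so default Otsu segmentation recovers every object,
  because these fixtures test measurement, not detection limits.
* **Time-lapses**: one mitochondrion pair per event in its own tile,
  joined by a Gaussian focus for the drawn dwell time with positional
  jitter of σ 0.5 px/frame; fused pairs are bridged into one component
  from the frame after the event. Dwell distributions are point masses
  or shifted exponentials; draws overrunning the stack are truncated and
  recorded as censored (a point mass that cannot fit at all is a
  generation error). The foci channel carries no per-pixel background
  noise by default: the detector and linker are exercised by the
  positional jitter, and detection-limit behavior is not what these
  fixtures certify.
* **EM scenes**: mitochondria are fine 256-vertex circle polygons; each
  ER segment is an arc held at its programmed stand-off from the target
  circle (so its GAP is exact by construction), arcs on one
  mitochondrion occupy disjoint angular sectors, and stand-offs beyond
  60 nm appear in the scene but not the truth table. Truth coverage is
  computed from the projected angular sectors.
* **PA-GFP series**: components are bars of programmed area; the
  activated fraction fills the bar pixel by pixel, so any spread
  fraction is realized to single-pixel precision and the truth curve is
  exactly the ratio of spread fractions.

What the generators do **not** emulate: photorealistic textures, 3D,
uneven illumination, photobleaching, motile mitochondria, focal drift,
or segmentation-hostile noise. Passing tests therefore certify the
measurement chain — given resolvable objects, the statistics are right —
not robustness to acquisition pathologies.

## Numerical choices and degenerate inputs

Problem sizes in the test suite are chosen to run comfortably on a
laptop core: 100 simulated two-condition replicates for the dwell-ratio
recovery study (23 vs 18 events per replicate, 100 frames each), 100
cells for class recovery, 50 random traced scenes, 160-px rectangles for
the AR oracle sweep. Smoothing uses banded-matrix products with
row-normalized truncated kernels (exact edge handling); an all-background
image segments to an empty label map rather than an error; an empty
object list is an error for per-cell statistics (a cell with no
mitochondria has no defined mean AR); ties in greedy linking resolve by
scan order, which is deterministic. A single global seed drives every
stage through per-module derived streams, and each output CSV carries
the MD5 hash of the configuration that produced it; the full pipeline
rerun under the same configuration is byte-identical.

## Known limitations

The classifier's thresholds are explicit stand-ins for qualitative
categories; cells near a boundary (for example tubular fraction exactly
0.9) land in Intermediate by design rather than being forced into a
class. The greedy linker can mis-assign crossing foci that approach
within the link radius. Contact GAPs are reported per contact as one
number (mean or min), which flattens within-contact distance profiles.
The fusion assay assumes negligible bleaching over 10 min. None of these
affect the synthetic validation, but all are worth keeping in mind on
real data.
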