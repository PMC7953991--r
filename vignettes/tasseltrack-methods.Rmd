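---
title: "Measuring anthesis from time-lapse tassel imagery: models and methods"
author: "tasseltrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring anthesis from time-lapse tassel imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A maize tassel filmed against the sky is, for our purposes, a dark connected
silhouette whose central (main) spike thickens locally while its anthers are
extruded. `tasseltrack` treats anthesis as a one-dimensional process on the
spike: at capture-day frame rates, a position `s` on the spike (measured in
pixels from the tip) is *flowering* at time `t` when its measured width
`w(t, s)` exceeds its own pre-flowering baseline by a substantial fraction
of the swelling amplitude. The package's chain — detect, classify, track,
segment, skeletonize, crop, measure, summarize — exists to turn raw frames
into the surface `w(t, s)` and then into three quantities: where flowering
started (onset position as a fraction of the profiled spike), in which
directions it spread (toward the tip, the base, or both), and how long it
lasted (in capture days).

The chain assumes: one camera, at most two foreground tassels, sky-dominated
background brighter than the plants, approximately stationary tassel
positions disturbed only by wind, and a main spike that is the longest
branch of the tassel skeleton. All are properties of the field protocol the
synthetic generator emulates.

# The synthetic scene generator

Because every downstream stage is validated against ground truth, the
generator is first-class code, not a test fixture. It renders:

* a sky of configurable brightness with a low-frequency cloud texture,
* two procedurally grown tassels (curved main spike, lateral branches
  attached on the lower spike, hard-edged silhouette in a dark brown),
* leaf-blob clutter and occasional faint background-row tassels,
* per-frame wind jitter (Gaussian translation) and missing-tassel frames,
* the anthesis process itself: a two-sided piecewise-linear front that
  starts at `onset_fraction` of the spike from the tip at `start_frame`,
  covers spike fractions `[onset - up_rate * e, onset + down_rate * e]`
  after `e` frames, holds for `duration_frames`, and adds `amplitude`
  pixels of width wherever it covers.

Default study conditions, chosen once: 240×320 px scenes; spike length
~140 px; base width 5 px (odd widths render exactly on the pixel lattice);
amplitude 6 px; onset fraction 0.65 from the tip (anthesis typically starts
about two thirds of the way down the spike); spread rates 0.004 spike
fractions per frame; duration 144 frames, i.e. two capture days at the
10-minute cadence (72 frames between 7 am and 7 pm; manifest timestamps
jump overnight while frame indices stay contiguous); jitter sigma 2 px and
missing-tassel probability 0.03 (wind and occlusion rates are not
quantified by any field source we rely on, so these are free, fixed
parameters); branch attach fractions 0.06–0.20 from the base, reflecting
that tassel branches emerge from the lower spike while the upper spike is
the unbranched part whose width is profiled.

What the generator deliberately does **not** emulate: photo-realistic
texture, lens optics, plant growth between frames, rain/fog artifacts, and
anther or pollen rendering — the swelling step stands in for all of the
latter. Passing tests therefore demonstrate that the measurement chain is
correct and well-conditioned on clean geometry, not that any particular
detector or segmenter is robust to real field imagery.

A half-pixel tolerance is applied to the front's coverage test in both the
renderer and the analytic truth profile so that a zero-spread front still
covers its single onset position on the integer lattice.

All randomness derives from one master seed through hashed sub-streams
(`substream_seed`), so sky texture, clutter and per-tassel jitter are
independently reproducible frame by frame.

# Detection, metrics and their conventions

Boxes are half-open pixel rectangles; IOU uses continuous areas, which
equals the pixel count under the half-open convention. The evaluation
follows the strict overlap rule: a prediction is true only if its IOU with
an unmatched same-frame ground-truth box exceeds 0.5; matching is greedy in
descending score with each ground-truth box matchable once (the matcher is
our choice; score-greedy matching is the common convention). Average
precision integrates the interpolated precision envelope over all recall
points; the 11-point convention is available as a switch. With one class,
mAP equals AP.

The quality-control rule defaults to fractions of the frame (minimum area
`4e-4 * H * W`, width and height within 1–90% of the frame, at most two
boxes kept, largest first with ties to the smaller `x_min`) because the a
priori annotation bounds used in the field were never published. The kept
score threshold is deliberately low (0.05): thresholding detector
confidence trades false negatives against false positives with no good
operating point, so the classification stage does the real screening.

The classifier metric suite implements the no-true-negative accuracy
`TP / (TP + FP + FN)` exactly as the field reports it — this is the Jaccard
index of the positive class and is never larger than precision or recall —
while the standard accuracy is exposed separately as `accuracy_standard`.
Degenerate 0/0 ratios return 0 with a `degenerate` flag rather than
raising, so a pipeline keeps running over empty frames.

# The trainable models

No deep-learning framework is assumed: the package carries a compact
convolutional engine (im2col convolution via BLAS matrix products, 2×2 max
pooling, nearest-neighbour upsampling, ReLU, dropout, softmax or per-pixel
sigmoid heads, Adam and SGD). Every layer's gradients are verified against
central finite differences in the test suite. The classifier follows the
published architecture sketch: 28 3×3 filters per convolutional layer, max
pooling after each, ReLU, flatten, dropout, 2-way softmax; the number of
conv blocks (default 3) and dropout rate (default 0.25) are configuration
because the source only fixes the filter shape. Crops are letterboxed
(aspect-preserving resize onto a padded square) since no resize policy was
published. The encoder–decoder is symmetric (default two levels of eight
and sixteen filters, a bottleneck conv, nearest-neighbour upsampling) with
per-pixel binary cross-entropy and a 0.5 probability cutoff. The loss
weights foreground pixels by the inverse foreground fraction of the
training masks (capped at 20): a letterboxed tassel silhouette covers only
a few percent of its crop, and the unweighted loss can converge to the
all-background solution — high pixel accuracy, zero foreground IOU — which
class weighting prevents.

Training studies run at desk scale: 200 crops or 100 crop/mask pairs at
64×64, batch size 32 or 16, learning rate 1e-3, up to 20 or 30 epochs with
early stopping once validation accuracy reaches 0.95/0.97. These sizes are
the package's chosen study conditions; the separable synthetic regime is
easy by construction, which is exactly what a learning *sanity* check
requires.

# Tracking

All box centres of a sequence (at most the two largest boxes per frame) are
pooled and clustered by `stats::kmeans` with k = 2, ten restarts, squared
Euclidean distance on raw pixel coordinates. Identities are named left and
right by ascending cluster-centre x. When one frame contributes two boxes
to the same cluster, the box nearer the other cluster's centre is
reassigned, guaranteeing one box per identity per frame; each reassignment
is flagged. Clustering is global over the sequence (batch, not online),
matching how the centre scatter is actually bimodal under the two-plants-
per-camera protocol.

# Segmentation

The four classical segmenters are: Otsu's threshold on luminance (darker
side = tassel), and fixed-channel cutoffs in RGB (red < 0.45), HSV
(value < 0.55) and CIELAB (L < 55). The channels and cutoffs are tuned to
the synthetic palette and are configuration, not published values. The
consensus-annotation workflow scores all four candidates against a
reference mask by foreground IOU and selects the argmax, rejecting the crop
when even the best candidate scores below 0.5 (the human reviewer's
criterion was never quantified; 0.5 is our declared proxy). Without a
reference it writes the crop and candidates to a review directory with a
`selection.json` sidecar for a human decision.

Segmentation quality uses pixel accuracy and per-class IOU averaged over
foreground and background (mIOU). A class with an empty union contributes
IOU 1 so that all-background crops remain scoreable.

# Spike morphometry

The mask's largest 8-connected component is thinned to a one-pixel skeleton
(Zhang–Suen) and converted to a pixel graph; diagonal adjacencies shortcut
by a shared axial neighbour are dropped. Two skeleton-hygiene steps matter
in practice:

* **Spur pruning.** Thinning sprouts short dead-end chains wherever the
  outline has a corner — most importantly at the shoulders of the hard
  swelling step. Their junctions would masquerade as branch points and
  truncate the spike crop at the swelling edge, so dead-end chains shorter
  than 8 px that terminate at a junction are removed (real branches in all
  study conditions are at least ~20 px). Junctions within 3 px of each
  other along the path are additionally merged.
* **Smoothed arc length.** The raw 8-connected chain zigzags and overstates
  arc length by 1–2%, biasing tip-anchored positions toward the base.
  Profile *positions* are therefore measured along a 5-point moving-average
  smoothed polyline of the path. Path *selection* still uses the exact
  8-connected step weights (1 axial, sqrt(2) diagonal).

The base is the endpoint with maximum y (ties to smaller x; the image
convention is origin top-left, y downward, so the tassel tip has smaller y
than the base). The main spike is the maximum-weight simple path from the
base to any endpoint; ties break to the smaller tip y, then smaller tip x.
The search collapses degree-2 chains into weighted segments between
endpoints/junctions and enumerates simple segment paths exactly — simple
pixel paths correspond one-to-one to simple segment paths because a simple
path visits each junction pixel at most once — which stays exact and fast
even when thinning leaves small loops.

The spike crop keeps foreground pixels whose nearest path node (ties
resolved tipward) lies strictly beyond the topmost branch point, i.e. the
junction with the greatest along-path distance from the base; a junction at
the base itself is excluded, and a branchless tassel keeps its whole
region. "Topmost" is along-path nearest-to-tip rather than minimum y,
which is robust to curved spikes.

Width at a path node is `2 d − 1` pixels, where `d` is the Euclidean
distance-transform value of the crop foreground at the node. The `−1`
calibrates the lattice: a one-pixel line has `d = 1` at its own pixels and
true width 1; a five-pixel bar has centre `d = 3` and true width 5. (The
plain `2 d` convention overstates odd widths by one pixel; even widths are
off by one pixel under either convention, which the ±1-px discretization
tolerance of all width checks absorbs.)

# Anthesis surfaces and summaries

Profiles are anchored at the tip because the profiled length varies frame
to frame — a moving branch can occlude the main spike and shift the
detected topmost branch point — so only tip-anchored positions are
comparable across time. Rows are padded with invalid cells beyond each
frame's profiled length.

Outlier removal is a robust temporal despiking: a cell is invalidated when
it deviates from its column's running median (window 9 frames) by more than
3.5 robust deviations (MAD floored at 0.5 px for lattice noise) *and*
differs from both temporal neighbours by the same margin. The second
condition distinguishes isolated excursions (occlusion artifacts) from the
leading edge of a genuine flowering step: piecewise-constant columns have
MAD ≈ 0, and without the spike guard the first cells of every real step
would be discarded. The operation is idempotent and can only shrink the
valid set.

The flowering summary estimates, per position, the baseline width as the
median over the first `baseline_frames` frames (the caller guarantees these
precede swelling; the pipeline defaults to two thirds of a capture day).
The swelling amplitude is estimated as the 95th-percentile excess over
baseline across the surface; if that estimate is below 2 px, no flowering
is reported — this floor prevents a flat, noisy surface from triggering on
its own noise quantiles. A cell is flowering when its excess exceeds half
the estimated amplitude (`swell_threshold = 0.5`). Onset is the first
flowering frame; because the rendered front has spatial extent (the disc
radius), several adjacent columns flip together at onset, and the onset
position is the median flowering column of that frame. Duration is the
frame span between the first and last flowering frames divided by
frames-per-day, i.e. expressed in capture days (a "day" is the 7 am–7 pm
window). Spread directions compare the outermost flowering columns of the
episode against the onset position with an 8 px margin. Raising
`swell_threshold` shrinks the flowering set, so the detected duration is
monotone non-increasing in it.

# Recovery studies and their conditions

`anthesis_recovery_study` sweeps onset fractions 0.3–0.8 and durations
1–3 capture days over 20 seeded single-tassel mask sequences at 72
frames/day and compares the recovered onset (as a fraction of the true
spike length) and duration against the generator's parameters. Its tassel
architecture is chosen so the measurement is observable across the whole
sweep: a low branch whorl (attach fractions 0.04/0.07) so the profiled
crop reaches 0.8 of the spike from the tip with room below, short
opposite-side branches (21 px) and mild curvature (±0.08) so the swelling
front never fuses with a lateral branch. Frames sharing a swelling interval
render identical masks and are measured once.

`width_recovery_study` measures profile error against analytic truth over
25 random shapes, half with active swelling; `tracking_recovery_study`
checks box-to-identity agreement over 20 scenes whose tassel separation is
at least four times the jitter sigma; the two learning studies train the
classifier (10 seeds) and segmenter from scratch on separable synthetic
data. All quantitative outcomes of these studies are computed by the test
suite and `scripts/acceptance.R`; this vignette intentionally states none
that are not.

# Known limitations

* **Branch occlusion / fusion.** When the swelling front reaches the branch
  whorl, the thickened spike can fuse with a branch; the topmost branch
  point then jumps tipward and truncates the visible crop. Tip-anchoring
  keeps the surviving positions comparable, but spread *below* the fusion
  point becomes unobservable. In particular, at onset fractions near 0.8 —
  directly above the whorl — the downward spread direction is only
  marginally observable and can fall below the 8 px direction margin for
  some shape draws. Onset and duration recovery are unaffected.
* The hard width step is an idealization; real anther extrusion is gradual
  and textured. A smoother front profile is a generator option, off by
  default, because crisp steps give exact recovery targets.
* Even target widths render one pixel narrow on the integer lattice; study
  conditions use odd widths.
* The classical reference detector assumes a bright, near-uniform sky; it
  is a stand-in that lets the pipeline run without trained weights, not a
  field-grade detector. External detectors integrate through the box CSV
  schema.
* The pipeline's default classification backend is the classical
  dark-fraction rule so an end-to-end run needs no training; the CNN
  backend slots in via `pipeline_config(classification = list(backend =
  "cnn", model_path = ...))`.
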