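# tasseltrack

Spatiotemporal anthesis extraction from time-lapse maize tassel imagery.

## The problem

In maize, anthesis — the emergence of anthers and shedding of pollen — begins
roughly two thirds of the way down the tassel's central spike and spreads
toward the tip and the base over several days. The amount and timing of
pollen shed drive hybrid seed production ("nicking" of the two parents), so
breeders want to monitor the spatiotemporal pattern of anthesis across many
genotypes under field conditions. When a pole-mounted camera images a pair of
tassels against the sky every 10 minutes of daylight, the local **thickening
of the main spike** is a visible proxy for flowering: a position on the spike
is shedding pollen when its measured width rises above its pre-flowering
baseline.

`tasseltrack` implements the full sequential measurement chain as an R
package, for plant-phenotyping researchers and image-analysis method
developers:

1. **Detection** — bounding boxes per frame (a classical reference detector
   for sky-backed scenes plus a CSV adapter for boxes from any external
   detector), annotation quality control, and evaluation by intersection
   over union (IOU) and mean average precision (mAP). A prediction counts
   true only when `IOU = area of overlap / area of union > 0.5`.
2. **Classification** — a small convolutional network (28 3×3 filters per
   conv layer, max pooling, ReLU, softmax) that removes false-positive
   boxes, evaluated by precision, recall, `accuracy = TP/(TP+FP+FN)` and F1.
3. **Tracking** — k-means (k = 2) on the pooled centres of the two largest
   boxes per frame associates every box with the left or right tassel.
4. **Segmentation** — four classical segmenters (Otsu, RGB / HSV / LAB
   channel thresholds), a consensus-annotation workflow, and a small
   trainable encoder–decoder, scored by pixel accuracy and mean IOU.
5. **Spike morphometry** — the binary mask is thinned to a skeleton graph;
   the longest base-to-endpoint path is the main spike, its far end the
   tassel tip; the spike is cropped between the topmost branch point and the
   tip; width at every path pixel comes from the Euclidean distance
   transform.
6. **Anthesis analysis** — tip-anchored width profiles stacked over time
   form a width(t, s) surface; after robust outlier removal, flowering
   onset position, spread directions and duration are extracted from the
   swelling above the per-position baseline.

Because the original field imagery is not publicly deposited, the package
ships a **procedural scene generator** that emulates the experiment's
statistical structure — two tassels against a bright sky, 10-minute cadence
over 7 am–7 pm, wind jitter, missing-tassel frames, leaf clutter, and a
controllable width-swelling anthesis process — with complete ground truth
(boxes, masks, skeleton paths, branch points, width profiles). Every stage
is therefore testable end to end without field data or trained weights.

## Worked example

Measure a swelling process from rendered masks and recover its parameters:

```r
library(tasseltrack)

sp <- tassel_spec(main_spike_length = 120, n_branches = 2,
                  branch_attach_fractions = c(0.05, 0.1), branch_lengths = 25)
an <- anthesis_model(onset_fraction = 0.6,      # starts 60% of the way down
                     up_rate = 0.004, down_rate = 0.004,
                     amplitude = 6,             # +6 px width while shedding
                     duration_frames = 144,     # 2 days at 72 frames/day
                     start_frame = 72)
frames <- 0:251
profiles <- lapply(frames, function(f)
  analyze_mask(generate_tassel(sp, an, f)$mask)$profile)
surface <- remove_outliers(align_profiles(profiles, frames = frames))
summarize_flowering(surface, baseline_frames = 48)
#> Flowering onset at 72 px from the tip (fraction 0.57 of the profiled spike)
#>   frames 72..215, duration 1.99 capture days; spread: upward + downward
#>   estimated amplitude 6.0 px (threshold 3.0 px over baseline)
```

The generator's truth puts the onset at 73.1 px from the tip, the swelling
amplitude at 6 px and the duration at 2 days: the chain recovers the onset
within about one pixel, the duration within a hundredth of a day, and sees
the front spreading both upward and downward — the mid-spike, bidirectional,
multi-day pattern expected of maize anthesis.

The classifier metric suite works the same way on real confusion counts:

```r
compute_metrics(confusion_matrix(tp = 7, fp = 0, fn = 1))
#> precision 1.0000  recall 0.8750  accuracy 0.8750  F1 0.9333
```

An end-to-end run over a simulated camera (detection → classification →
tracking → segmentation → analysis, with cached per-stage artifacts) is one
call — `run_pipeline(pipeline_config(seq_dir, out_dir))` — or one shell
command via the bundled CLI:

```sh
Rscript inst/cli/tasseltrack.R simulate --output seq --seed 4 --days 2
Rscript inst/cli/tasseltrack.R run-all  --input seq --output out --seed 4
Rscript inst/cli/tasseltrack.R evaluate --input seq --output out
```

## Package layout

- `R/synthetic-field.R` — scene/tassel/anthesis specifications, rendering,
  sequence writer with manifest and ground truth
- `R/detection.R`, `R/metrics.R` — boxes, QC, IOU/mAP, Eq.-style metric suite
- `R/nn-core.R`, `R/classifier.R`, `R/segmentation.R` — the compact conv-net
  engine and the two trainable models plus classical segmenters
- `R/tracking.R` — k-means track association and crop extraction
- `R/spike-analysis.R` — thinning, skeleton graph, longest path, branch
  points, spike crop, width profiles
- `R/anthesis.R` — surfaces, outlier removal, flowering summaries
- `R/pipeline.R` — stage orchestration, caching, run evaluation
- `R/studies.R` — seeded recovery studies used by the acceptance checks
- `vignettes/tasseltrack-methods.Rmd` — the model, its assumptions, and
  every numerical design choice
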