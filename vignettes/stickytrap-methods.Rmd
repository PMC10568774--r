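---
title: "Counting tiny pests on sticky traps: methods and design notes"
author: "stickytrap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting tiny pests on sticky traps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickytrap)
```

## The problem

Yellow sticky boards are the standard passive trap for flying greenhouse
pests. A fixed camera photographs a 20 x 25 cm board at high resolution
(here 3280 x 2464 px, about 13.1 px/mm), and the boxes on the board are the
raw material for population monitoring: count each insect, classify it, and
track the per-day counts over a season.

The difficulty is scale. The six pest classes span body lengths from 0.5 mm
(thrips) to 8 mm (houseflies). A single-stage convolutional detector with
strides 8/16/32 that squeezes the whole frame into a 608 px input can only
resolve objects down to the footprint of one cell of its finest feature
grid mapped back to the raw frame:

```{r geometry}
geometry_report()
```

That ~43 x 32 px floor is larger than most of the insects on the board — a
0.5 mm thrips spans about 7 px. The remedy implemented here is
*overlapping tile inference*: crop the frame into 600 px tiles (almost 1:1
with the network input), detect per tile, and merge. The same arithmetic on
a 600 px tile gives an 8 px floor, comfortably below a thrips.

## Overlapping tile grids

`plan_grid(W, H, tile)` uses `n = ceiling(dim / tile)` tiles per axis with
a uniform overlap `o = (n * tile - dim) / (n - 1)`. Fractional overlaps are
made integral by adding the remainder pixel-by-pixel to the earliest gaps,
so every origin is an integer and the last tile ends exactly at the image
edge. For the canonical 3280 x 2464 frame this yields 6 x 5 = 30 tiles with
64 px horizontal and 134 px vertical overlaps. The overlap matters: an
insect cut by a tile edge is seen *whole* in the neighbouring tile whenever
its box is smaller than the overlap, so boundary insects are not lost — the
cost is duplicate detections, which the merge step removes.

## DIoU-NMS: removing duplicates without merging neighbours

Plain greedy NMS suppresses any box whose IoU with a kept, higher-scoring
box reaches the threshold. On a trap this misbehaves: two insects sitting
side by side (whiteflies cluster) produce heavily overlapping boxes that
plain NMS collapses into one count. The distance-IoU criterion subtracts a
center-distance penalty

$$R(A, B) = \frac{\rho^2(a, b)}{c^2},$$

with $\rho$ the Euclidean distance between box centers and $c$ the diagonal
of the smallest rectangle enclosing both boxes, and suppresses only when
$\mathrm{IoU} - R \ge \varepsilon$. Duplicate detections of one insect have
near-coincident centers ($R \approx 0$) and are still removed; adjacent
insects have displaced centers, $R$ grows, and both are kept. Because
$R \ge 0$, the DIoU keep-set is always a superset of the plain NMS keep-set
at equal $\varepsilon$ — a property the test suite asserts on randomized
instances. Suppression uses the non-strict inequality (criterion exactly at
$\varepsilon$ suppresses).

Score ties are broken deterministically (lower class id, then
lexicographic coordinates), so results are reproducible across platforms.
The default $\varepsilon = 0.45$ is common detection practice and is
exposed in every entry point; suppression is per-class by default since
detectors report class-wise confidences.

## The merge step and partial views

`merge_detections()` translates per-tile boxes back by their tile origins,
pools them, clips to the image, and runs a *single* whole-image DIoU-NMS
pass (tiles are not pre-suppressed — one global pass keeps the suppression
decision consistent across tile seams).

Partial views need care. A pixel detector sees a fragment of an insect in
one tile and the whole insect in a neighbouring tile; a low-visibility
fragment overlaps the whole view too weakly for any NMS to remove it and
would double-count. `detect_image()` therefore drops per-tile boxes that
touch an *inner* tile edge (within 1 px): the whole view exists elsewhere.
Edges on the image border keep their boxes. The residual failure mode is an
insect wider than the horizontal overlap (houseflies can reach ~105 px
against a 64 px overlap) straddling an entire overlap strip, which then has
no whole view and is missed; with the default catalog this affects roughly
1% of insects and is the package's accepted limitation.

The oracle path (`oracle_detections()`, used throughout the tests) emits
clipped truth boxes with score equal to the visible-area fraction and a
0.6 minimum visibility. Both numbers are chosen analytically, not tuned: a
fragment with visible fraction $f$ of a whole box has
$\mathrm{IoU} = f$ against it and a center penalty bounded by
$((1-f)/2)^2 \cdot L^2 / c^2$, so for $f \ge 0.6$ the criterion
$f - R \ge 0.45$ always holds and whole views (score 1) win the merge.
This makes the end-to-end count identity exact for every placement the
generator produces, which the suite checks on 50 scenes.

## Evaluation

Matching is standard greedy: predictions in descending score order claim
the unclaimed truth with highest IoU at or above the threshold (default
0.5; the evaluation threshold is a toolkit choice). Precision, recall and
F1 follow the usual definitions with 0/0 read as 0. AP integrates the
all-point interpolated precision envelope of the PR curve (the COCO-style
definition, chosen over 11-point sampling); mAP averages classes present in
the truth. The confusion matrix matches class-agnostically so that a
well-localized but misclassified insect lands in an off-diagonal cell;
missed truths count as predicted background and spurious predictions as
background predicted-as-class, with row sums conserving per-class truth
counts.

## The synthetic scene generator

Real greenhouse imagery is not distributable with the package, so the
generator is the test substrate. It emulates, deliberately at the geometry
level rather than photo-realistically:

* a yellow board with a mild two-axis illumination gradient and Gaussian
  pixel noise (sd 0.015);
* six pest classes with mm body-length bands — housefly 5–8, leaf miner
  4–6, fruit fly 1.5–4, winged aphid 2.2 widened to 1.8–2.6 for sampling
  variety, thrips 0.5–2, and tobacco whitefly 1.0–1.5 (the whitefly length
  is an assumption; it is not part of the published description) — drawn
  as rotated dark ellipses, whiteflies whitish, winged classes with a
  lighter wing streak; class frequencies default to the 1024 : 857 : 1092 :
  941 : 873 : 1013 proportions of a real training set;
* dust-like distractors at 0.1–0.3 mm, all below the thrips size band, at
  about 40 specks per megapixel by default;
* an exact truth box per insect: the analytic bounding box of the rotated
  ellipse footprint.

Placement is rejection-sampled so boxes do not overlap (3 px margin) unless
`allow_overlap = TRUE`, which creates the adjacent-pair regime that
separates DIoU-NMS from plain NMS. All randomness flows through one seeded
RNG per scene; series scenes derive per-day seeds as `seed + day`, so the
truth is identical whether or not pixels are painted.

What passing tests on this substrate do show: the tile bookkeeping,
suppression logic, metric definitions and monitoring aggregation are
correct, and a very simple color detector suffices to localize
ellipse-like insects. What they do not show: performance on real imagery,
where insects are textured, limbs smear, illumination varies more, and
dust can be insect-sized. The reference detector exists to exercise the
pipeline, not to claim field accuracy, and its precision/recall checks are
therefore class-agnostic — its classifier is a size-band heuristic over
overlapping mm ranges and cannot distinguish, say, a large thrips from a
small aphid.

## The reference detector

Per tile: estimate the board color as the per-channel median of a strided
pixel sample; threshold the Euclidean color distance at 0.35; label
connected components; drop blobs with fewer than 3 px or a major axis below
0.45 mm (just under the smallest thrips, so dust never passes); box each
blob from its pixel extent; classify by major-axis length against the
catalog bands (light blobs to the whitefly class); score as blob solidity
times a band-membership factor (0.6 off-band).

## Time-series monitoring

`aggregate_counts()` turns per-day global detections into a day x class
count table with totals and running cumulative sums. Days come from the
manifest (never parsed from file names); missing days are gaps, not zeros.
Counts are raw per-frame counts — sticky boards accumulate insects, so the
curves are cumulative-like by nature and no detrending is applied. The
default simulated season (`outbreak_profile()`) is a 40-day curve with a
low start around 37/day, a sharp burst to 325 on day 10, a decay to ~92,
and a fluctuating late plateau up to ~419 — the qualitative shape of
observed greenhouse outbreaks.

## Mosaic and tile training sets

For training-set construction the package provides classic four-image
mosaic augmentation (random center split, per-patch right-angle rotation,
flip, scale, brightness/hue jitter, with boxes transformed exactly and
dropped below 4 px²) and `build_tile_training_set()`, which expands each
annotated frame into its full overlapping tile set with clipped YOLO-txt
labels (a canonical frame yields 30 tiles; empty tiles are kept as
negatives). Rotation is restricted to right angles because axis-aligned
boxes cannot represent arbitrary rotation without loose re-fitting. The
clipping visibility threshold defaults to 0.25 for training data — a
partially visible insect is still a useful positive; the stricter 0.6 is
reserved for the oracle-detection path described above.

## Numerical and scale choices

* Coordinates are continuous, 0-based, half-open; no rounding inside
  geometry operations. Degenerate boxes are rejected at construction.
* Grid planning, cropping and clipping are integer-exact.
* The suite runs the oracle identity on 50 full-frame scenes (truth-only
  rendering, which skips pixel painting) and the reference detector on 8
  rendered frames totalling several hundred insects; the 40-day monitoring
  identity uses truth-only scenes. These sizes keep the default check
  fast while exercising every code path at the canonical frame geometry.
* PNG output is 8-bit; generator determinism is asserted on the in-memory
  arrays, and file round-trips are asserted to quantization precision.

## Known limitations

Insects wider than the horizontal tile overlap can be missed when they
straddle a full overlap strip (see above). The size-band classifier is
intentionally weak for overlapping bands. The generator does not model
insect texture, motion blur, specular glue reflections, or trap aging;
conclusions about real-world per-class accuracy require real annotated
imagery fed through the same evaluation module.
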