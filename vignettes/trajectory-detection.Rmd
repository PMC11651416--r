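---
title: "Detecting maize leaf and stalk trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting maize leaf and stalk trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maizetraj)
```

## The problem

Field phenotyping of maize needs two quantities that are awkward for
standard detectors: how many leaves and stalks a scene contains, and where
each one's *growth trajectory* runs. Segmentation masks over-describe a
trajectory (most pixels of a leaf are irrelevant to its midrib) and plain
bounding boxes under-describe it. The annotation style this package works
with is the dotted line: each instance is a category (`leaf` or `stalk`)
plus an ordered list of points tracing its path. Heavy mutual occlusion in
closed canopies is the central difficulty; everything below is shaped by it.

`maizetraj` implements the full workflow around that annotation style:

1. **Annotation engineering** — reading Labelme-dialect JSON, downscaling
   coordinates with the images, synthesizing detection boxes from point
   extrema, interpolating the sparse hand-labeled points along the
   trajectory, and subsampling them at equal intervals into ground-truth
   keypoints.
2. **A two-stage detector with a single-heatmap keypoint branch** — a
   convolutional backbone with a feature pyramid, a region proposal
   network, an RoIAlign box head, and a lightweight branch that predicts
   *all* of an instance's trajectory points in one probability grid.
3. **Suppression for occluded scenes** — Soft-NMS with Gaussian score
   decay, optionally using distance-IoU as the overlap measure.
4. **Evaluation** — precision/recall/AP/mAP for the boxes, and the mean
   line distance (mLD) for the trajectories.
5. **A synthetic scene generator** so that every stage is testable without
   any external imagery.

## The model

### Two-stage detection

The detector follows the Faster R-CNN lineage. A backbone produces a
feature pyramid (1x1 lateral convolutions, nearest-neighbor top-down
upsampling, 3x3 smoothing); each pyramid level carries anchors of one area
(the full-scale profile uses five areas, $32^2$ through $512^2$ px, with
aspect ratios 0.5/1/2). A shared RPN head scores anchors and regresses box
deltas; decoded proposals are clipped, filtered, and suppressed (the
full-scale profile retains 4000 before and 2000 after RPN suppression —
raised from the common 2000/1000 because maize scenes hold many close
targets). RoIAlign (output 14 in the full-scale profile) pools each
proposal's features for a small fully connected head that classifies
(leaf / stalk / background) and refines the box.

### The single-heatmap keypoint branch

Trajectory points are not anatomical landmarks: any point on the midrib is
a correct "keypoint", and their number varies per instance. A conventional
keypoint head (one heatmap channel per named keypoint) cannot represent
that, so the keypoint branch here predicts **one** single-channel heatmap
per detection, consuming the same proposals as the box head. Training
targets are rendered by mapping each ground-truth keypoint into the
box-registered grid and drawing an unnormalized Gaussian (peak exactly 1 at
the keypoint's cell, scale `sigma_hm = 2` cells); overlapping Gaussians
combine by pointwise maximum, so any number of points coexist in the one
channel. The loss is mean per-cell sigmoid binary cross-entropy. A spatial
softmax (the usual choice when each channel holds exactly one landmark)
cannot represent multiple peaks in one channel, which is why the per-cell
formulation is used.

At inference, peaks are extracted from the sigmoid heatmap: strict local
maxima over the 8-neighborhood, value at least `value_threshold` (default
0.3), kept greedily in descending value order with a Chebyshev separation
of `min_separation` (default 2 cells), at most `max_points` (default 32),
ties broken by (row, column) order so extraction is deterministic. Kept
cells map back to image coordinates through the inverse of the box-to-grid
affine map. Box-level suppression runs *before* peak extraction; a
suppressed detection contributes no keypoints. The extracted points are
deliberately left unordered — the evaluation metric needs no ordering on
predictions.

### Suppression under occlusion

Hard NMS deletes every box whose IoU with a kept higher-scoring box
exceeds a threshold, which is exactly wrong for clustered leaves. Soft-NMS
instead decays scores: when a box is kept, every remaining same-class box's
score is multiplied by $\exp(-o^2/\sigma)$, where $o$ is its overlap with
the kept box, and boxes falling below `score_floor` are dropped. The decay
form and $\sigma$ are not pinned down by the sources this design follows,
so the reference Gaussian defaults are used ($\sigma = 0.5$, floor
0.001; the detector pipeline floors at 0.05 to keep evaluation-time
detection lists short).

Distance-IoU sharpens the overlap measure with a center-distance penalty:

$$\mathrm{DIoU} = \mathrm{IoU} - \frac{\rho^2(b, b^{gt})}{c^2}$$

with $\rho$ the Euclidean distance between box centers and $c$ the diagonal
of the smallest enclosing box. Since $\mathrm{DIoU} \le \mathrm{IoU}$
always, Gaussian decay driven by DIoU (negative values clamped to 0) is
never stronger than IoU-driven decay: boxes that overlap but sit apart are
punished less, which is the behavior wanted in dense canopies. `soft_diou`
is therefore the pipeline default.

## The mean line distance

Let a matched detection have $M$ predicted points and its ground truth have
$G$ ordered points. The distance of predicted point $i$ to the trajectory
is the minimum over the $G-1$ consecutive segments of the point-to-segment
distance, computed from the projection parameter $t = C/\lVert AB\rVert^2$
(with $C$ the inner product of $\vec{AB}$ and $\vec{AP}$): distance to $A$
when $t \le 0$, to $B$ when $t \ge 1$, else to the perpendicular foot. Then

$$LD_k = \frac{1}{M}\sum_{i=1}^{M} \min_{g} D(x_i, y_i; x_g, y_g, x_{g+1}, y_{g+1}),
\qquad mLD = \frac{1}{K}\sum_{k=1}^{K} LD_k$$

over the $K$ matched targets. mLD is measured in pixels at working
resolution and scales linearly with the image scale.

Two points in this definition are genuinely open and were decided as
follows:

* **Correspondence.** "The corresponding real target" needs a matching
  rule. We use greedy one-to-one matching in descending score order,
  class-aware, accepting a pair when box IoU reaches 0.5 — the same
  matching family AP already requires. Unmatched detections and ground
  truths are excluded from mLD but reported alongside it; detection-quality
  failures are mAP's job, and folding them into a distance would make the
  metric uninterpretable.
* **Degenerate segments.** A zero-length segment contributes its endpoint
  distance (it cannot define a foot), and the written formulation's use of
  the segment length is resolved so that all returned distances are
  Euclidean pixels; the projection parameter divides by the *squared*
  length, which is what makes the perpendicular-foot formula correct.

OKS, the standard keypoint metric, is deliberately not implemented: it
assumes identified landmarks with per-landmark tolerances, which
contradicts the interchangeable-point annotation this task uses.

## Annotation engineering choices

* **Interpolation** of the sparse hand-labeled points is piecewise-linear
  by arc length with a spacing parameter (default 5 px at working
  resolution; the synthetic pipeline uses 3 px at its smaller scale):
  output points lie exactly on the annotated polyline and consecutive
  points are at most the spacing apart. Nothing in the task rewards a
  smoother interpolant, and a curved one would move points off the
  annotated path.
* **Subsampling** keeps $k = \max(2, \mathrm{round}(n \cdot r))$ points
  ($r = 0.3$ by default) at equally spaced *indices*, always including both
  endpoints so the trajectory's extent survives. Index space rather than
  arc length: after interpolation the points are already near-uniform along
  the arc, and index selection keeps the output an exact subsequence.
* **Box synthesis**: the point extrema give the corners, padded outward by
  an offset (20 px at the 1504x1004 working scale) and clipped to the
  image; zero-area boxes are rejected. The offset is applied in the
  *downsampled* coordinate space, where the quoted value sits alongside the
  working resolution; at other scene scales the pipeline scales the pad
  proportionally (6 px at 256x256).
* **Splitting** is a seeded uniform shuffle followed by largest-remainder
  apportionment to the 7:2:1 ratios, so split sizes always sum to $n$ and
  the same seed reproduces the same partition.

## The synthetic scenes

The generator emulates the *structure* of camera-view maize field imagery:
multi-plant scenes, near-vertical 5-point jittered stalk polylines, leaves
as 20-point quadratic Bezier arcs rooted on the stalk, drawn as thick
anti-aliased strokes in green-hue palettes over plain or cluttered soil
backgrounds. Stage presets (`early`, `middle`, `late`) raise plant count,
leaf count, and leaf length so that late-stage scenes have strictly more
inter-instance box overlap — the property that makes occlusion-aware
suppression testable. Every drawn curve's centerline *is* its annotation,
so ground truth is pixel-faithful by construction. All randomness flows
from one seed through a fixed per-scene affine step.

What the generator does **not** emulate: photorealistic texture, lighting
variation, UAV viewpoints, wind motion blur, or the label noise of human
annotators. Passing the end-to-end tests therefore demonstrates that the
architecture, losses, and metrics are implemented coherently and that the
detector can learn shape-and-color structure under occlusion — not that
this configuration would reach any particular accuracy on real field
imagery, which needs the full-scale backbone profile and real data.

## Training

Optimization is stochastic gradient descent with momentum 0.9, weight
decay $10^{-4}$, and a step schedule: learning rate
$\mathrm{lr}(e) = \mathrm{lr}_0 \cdot \gamma^{\lfloor e/s \rfloor}$ with
the full-scale defaults $\mathrm{lr}_0 = 10^{-3}$, $\gamma = 0.66$,
$s = 10$, over 200 epochs. Augmentation is random horizontal flipping
(every x-coordinate maps to $w - 1 - x$; box corners re-sorted) and random
per-channel color gain; jitter never touches coordinates. Per-image
training steps supervise the RPN on 64 sampled anchors (positives at IoU
0.7 or each ground truth's best anchor; negatives below 0.3), the box head
on 32 sampled proposals (foreground at IoU 0.5, ground-truth boxes added
to the pool), and the keypoint branch on up to 8 foreground proposals with
targets rendered in the *proposal's* box frame, so the branch learns the
same registration it will see at inference. The best checkpoint by
validation mAP50 is retained.

Because the package trains from random initialization with batch size 1,
every convolution is followed by per-channel instance normalization
(per-sample spatial statistics, learnable gain and shift). Batch statistics
do not exist at batch size 1, and without normalization this regime
collapses into dead rectifier units; with it, the tiny profile trains
stably at a learning rate of 0.02. Gradients are clipped to a global norm
of 10. Backpropagation treats proposal boxes as constants (no gradient
through box decoding into RoIAlign coordinates), the standard two-stage
practice.

The `tiny_fpn` profile — two pyramid levels (strides 4 and 8), 16 pyramid
channels, anchors of areas $24^2$/$64^2$, RoIAlign 7, heatmap 28 — exists
so the whole pipeline trains on one CPU. The named full-scale profiles
(`resnet101_fpn` default, `resnet50_fpn`, `mobilenet_fpn`) keep the stage
layouts (depths, widths, strides, five pyramid levels) of the
architectures they are named after, built from basic 3x3 residual blocks;
they define the configuration contract and are not exercised by the
CPU-scale tests beyond construction.

### Study problem sizes

The package's reference experiment (`synth_experiment()`, also what
`scripts/acceptance.R` runs) uses 200 scenes of 256x256 px alternating the
early and middle presets, split 140/40/20, trained for 8 epochs. These
sizes were chosen as the smallest configuration at which held-out detection
and trajectory quality are comfortably measurable; the oracle suites use
1000 random geometry instances, 500 heatmap round-trips, and 200
suppression instances.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based pixels; boxes are inclusive-corner
  $(x_1, y_1, x_2, y_2)$ with area $(x_2-x_1)(y_2-y_1)$; IoU of a
  zero-area union is defined as 0; DIoU of two boxes degenerate to the
  same point is an error.
* The heatmap grid cell of an image point is
  $\lfloor (x - x_1)/w \cdot S \rfloor + 1$ (clamped); a cell maps back to
  its center. A round trip therefore moves a point by at most half a cell's
  image extent.
* A single-point polyline is a point target; identical consecutive
  polyline vertices are skipped as zero-length segments.
* `subsample_equal_interval` of a single point returns it unchanged;
  densifying a zero-length polyline returns the single distinct point.
* Peak-extraction ties and all sampling are deterministic under the run
  seed; repeated runs with one seed are byte-identical.

## Known limitations

* The from-scratch CPU regime is not the full-scale regime: no pretrained
  backbone, small images, and instance rather than batch normalization.
  Absolute numbers from the synthetic experiment say nothing about real
  field accuracy.
* mLD depends on the matching rule (choices above); comparisons across
  implementations are only meaningful under the same rule.
* The keypoint branch caps extracted peaks (`max_points`, default 32);
  pathological heatmaps with more genuine peaks than the cap would be
  truncated, highest peaks first.
* Leaves are single arcs; real maize leaves bend in 3-D and cross their
  own plant's stalk, which the generator only partially imitates.
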