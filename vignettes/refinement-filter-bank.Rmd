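---
title: "Refining plant-disease detections with a per-class verifier bank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining plant-disease detections with a per-class verifier bank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refinebank)
```

## The problem

Object detectors for greenhouse disease diagnosis emit scored bounding
boxes $b_i = \{s_i, l_i, c_i\}$ (size, location, class score) for each
image. On class-unbalanced data — the tomato benchmark this package is
calibrated to has 24% of its boxes in one class and under 1% in three
others — roughly one box in ten is a false positive, and rare classes with
large intra-class variation are confused with lookalikes (gray mold with
canker, canker with plague). False positives directly depress precision,
so a second opinion targeted at exactly the boxes the detector emits is an
effective repair.

`refinebank` implements that second opinion as a *filter bank*: one
independent binary CNN per class. Each verifier sees the patch under a
detection of its class and answers whether the patch truly depicts that
class (`TRUE`) or not (`FALSE`). The integration stage keeps `TRUE` boxes
and drops the rest, leaving boxes, labels and scores of survivors
untouched. Because the recall of the primary detector caps what the
pipeline can find, the design goal is to fix recall (retain the true
positives) while raising precision (discard the false positives).

## Evaluation model

Evaluation follows the Pascal VOC protocol. A detection matches a
ground-truth box of the same class in the same image when their
intersection-over-union,
$\mathrm{IoU}(A,B) = |A \cap B| / |A \cup B|$, reaches the threshold
(default 0.5; the comparison is `>=`, so a threshold of 1 still admits
exact matches, with a `strict` switch for `>`). Matching is greedy in
descending score; each ground-truth box may be claimed once; duplicates
are false positives. Score ties break by input order and IoU ties by
lowest ground-truth index, making every result deterministic. True
negatives are undefined for open-background detection and are always
reported as not-applicable.

Average precision is the 11-point interpolated form: the mean of
$P_{\mathrm{interp}}(r) = \max_{\tilde r \ge r} p(\tilde r)$ over
$r \in \{0, 0.1, \dots, 1\}$, and mAP averages the classes that have
ground truth. Classes with zero ground-truth boxes are excluded from the
mean rather than scored 0 — scoring them 0 would penalize small synthetic
runs for classes that simply never appeared — and are listed explicitly
in the report.

Boxes use a 0-based, half-open pixel convention internally, so areas and
IoU are exact rational arithmetic on integer-aligned boxes. Pascal VOC
XML, which is 1-based and inclusive, is converted on the way in
(`x_min = xmin - 1`, `x_max = xmax`) and back on the way out.

## The detector simulator

The real primary detector (a Faster R-CNN) is out of scope; the
`detector_config()`/`simulate_detections()` pair stands in for it as a
calibrated noise model with a pluggable interface (`simulated_detector()`
documents the contract a real detector must meet). Per ground-truth box it
applies a miss probability (default 0.05), Gaussian edge jitter (default
2–3 px), and a row-stochastic label-confusion matrix; per image it injects
Poisson-distributed spurious boxes with uniform centers and log-uniform
sides between 16 px and half the image side, so both canonical patch
scales are exercised. Scores are truncated Gaussians on $[0,1]$ (means
0.85 for true boxes, 0.55 for spurious ones, sd 0.1), so score ranking
matters during matching. `calibrate_fp_rate()` solves for the spurious
rate that makes injected boxes a target share of all boxes — 10.03% by
default, the false-positive share of the benchmark's primary detector.
Label confusion adds a further small FP mass on top of the spurious
channel; the calibration deliberately targets the spurious channel only,
which keeps the solved rate interpretable.

## The verifier bank

Patches are extracted at native resolution, scale-adapted to one of two
canonical squares (300 and 500 px by default; routing by the longest
source-box side against a 150 px cutoff), and resized to the network
input. The verifier is a compact CNN: one to five 3x3 convolution blocks
(widths 16, 32, 64, 128, 128, each with ReLU and 2x2 max-pooling)
followed by a 256/64/2 fully-connected head and a softmax. Inputs are
centered to [-0.5, 0.5] on entry (all-positive inputs condition the
early layers poorly: at depth 5 the net separated classes but with a
vanishing logit scale), and all resampling toward the network input is
anti-aliased (iterative 2x2 mean halving before the final bilinear
step), without which 1-3 px lesion features alias away and the
fine-spotted classes become unlearnable at 64 px. The convolution
arithmetic is implemented as nine shifted BLAS multiplies per layer,
which keeps CPU training deterministic and fast enough for desk-scale
studies; gradients are verified against finite differences in the test
suite.

Training sets per class follow the hard-negative recipe: positives are
the patches of TP detections of the class; negatives are the FP
detections *assigned to* the class, topped up with background patches to
a 1:1 balance — the mitigation for class unbalance at the verifier level.
The split is stratified 80/20 by default. Training is Adam on the
cross-entropy (defaults: 6 epochs, batch 8, learning rate 1e-3 — small
batches give the rarest classes enough gradient steps, and higher rates
showed late-training divergence on easy classes), fully seeded, with no
dropout so inference is deterministic. The decision threshold is 0.5 with a `>=` verdict rule;
both are configurable per verifier.

Two readings of the source design were genuinely open and were settled as
follows. First, how a box chooses its scale is unstated; we route each box
to a single scale by its longest side rather than feeding both scales,
the simplest reading of a control block that "adapts sizes and feeds"
the networks. Second, consecutive training with *shared convolution
weights* contradicts the verifiers being independent networks; we train
the units sequentially (detector output first, then each verifier
independently) and do not share weights, since the sharing mechanism is
not implementable as described.

## Synthetic scenes

The generator emulates the statistical structure of the benchmark
dataset, not its photographic appearance: ten disease classes whose box
frequencies follow the benchmark's annotation shares (renormalized
without background), heavy unbalance included; two confusable pairs
(gray mold/canker and canker/plague share near-identical base colors and
differ only in lesion size and density); annotated background boxes as
negative training material; and per-pixel appearance noise as a
controllable difficulty axis. Scenes are 512x512 by default, with
Poisson(6) disease boxes of 32–160 px placed with pairwise IoU at most
0.5 and Poisson(2) background boxes. Everything is deterministic given
the seed, down to the PNG bytes.

What passing tests on these scenes shows is that the *mechanism* works:
a detector with ~10% false positives plus trained verifiers yields a
large precision gain at high TP retention, and the depth ordering of
verifier quality reproduces. What they cannot show is performance on real
tomato imagery — real lesions vary in ways flat textures do not, and the
real benchmark dataset is not public. The published per-class tables are
shipped as data (`tomato_primary_tp_fp()`, `tomato_annotation_counts()`,
`tomato_ap_by_class()`) so at least their arithmetic is reproduced
exactly.

The six standard augmentation families (resize, crop, rotation,
horizontal flip; brightness/contrast, color, noise) are provided by
`augment()`, with boxes transformed consistently: crops drop boxes
retaining under 25% of their area, rotations replace a box by the
axis-aligned hull of its rotated corners (exact for quarter turns).

## The benchmark and problem sizes

`benchmark_config()` fixes the package's end-to-end study: 200 scenes at
512 px, the full 10-class frequency vector, confusion leaks
canker→plague 0.10, gray mold→canker 0.10, low temperature→canker 0.05
(the confusions reported for the real detector), spurious rate calibrated
to 10.03%, verifiers of depth 5 at 64 px input, seed 1234. Per-class
training patches are capped at 75 per label by score rank; the cap and
the 64 px input keep a full run in the tens of minutes on one CPU while
leaving every class enough data to learn from. The depth study runs the
confusable-pair fixture (canker vs. plague textures, 24-48 px patches —
a regime where training converges at every depth, the precondition for
a meaningful depth comparison) through depths 1 to 5 at 32 px input and
10 epochs with a shared seed; the headline comparison is that the
depth-5 verifier ends at no worse held-out loss than the depth-1
verifier, the directional claim behind choosing depth 5. Full
monotonicity across all five depths is not asserted: single-seed
stochastic training does not support it, and the underlying claim is
directional.

## Numerical choices and degenerate inputs

Recall levels are computed as exact ratios (`(0:10)/10` against
`tp/n_gt`), so interpolation never misses a boundary recall by a rounding
ulp. Empty ground truth makes all detections FP (not an error); an empty
curve has AP 0. A jittered box that degenerates below 1 px^2 is resampled
up to 10 times, then skipped with a warning; a scene box that cannot be
placed within 100 attempts is dropped with a warning. Detection CSV
serializes coordinates to 2 decimals (the simulator produces sub-pixel
jitter); VOC XML uses integer pixels, and the generator emits
integer-aligned ground truth so the VOC round-trip is exact. Verifier
training aborts on non-finite loss and on single-label training sets.

## Limitations

The verifiers judge each box in isolation: no score recalibration, no box
regression, no cross-box context, no re-routing of a rejected box to a
different class. The simulator draws spurious-box labels uniformly over
the class set, which is the least-informative choice, not a fit to any
detector. mAP after refinement can move either way even when precision
improves — removing true positives of a rare class is penalized by that
class's AP but barely visible in micro-averaged precision — which is why
reports carry both, plus TP retention.
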