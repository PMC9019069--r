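---
title: "Methods: three-stage ASD detection on echocardiographic frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-stage ASD detection on echocardiographic frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

A secundum atrial septal defect (ASD) is a hole in the wall between the
left atrium (LA) and right atrium (RA). On color Doppler echocardiography
it appears as a jet of color-coded flow crossing the inter-atrial septum
(red toward the probe, blue away). Reliable image-level detection requires
three things: knowing which frames show a diagnostically useful view,
knowing where the atria (and hence the septum) are, and finding candidate
jets. `echoasd` chains these as three stages:

1. a five-way standard-view classifier routes frames — subcostal
   atrium-septum (subAS), apical four-chamber (A4C), low parasternal
   four-chamber (LPS4C), parasternal short-axis at the base (sax_basal),
   and "other" (integer codes 0–4, alphabetical with "other" last);
2. per target-view frame, an atrium segmentor and an anchor-free candidate
   detector run independently (their outputs never interact, so the
   contract is order-independence; they may execute concurrently);
3. deterministic refinement intersects the candidates with the septum
   band derived from the segmentation and makes image- and case-level
   calls.

The stage-3 anatomy prior is the heart of the design: a true ASD jet must
cross the septum, so any candidate that does not overlap the band
`hull(LA ∪ RA) − (LA ∪ RA)` (dilated for a decision margin) is a false
positive and is removed. Refinement can only remove candidates, so
precision and specificity rise while recall can only fall by the
(small) fraction of true jets that miss the band.

## Stage 1: knowledge distillation

The student is a ResNet-34 (basic residual blocks, layout 3-4-6-3); the
teacher is a ResNeSt-200 (split-attention bottlenecks with radix 2,
deep stem, average-pool downsampling, layout 3-24-36-3). Both are
constructible as exact layer descriptors: with 5 output classes the
student counts 21,287,237 trainable scalars and roughly 3.66 G
multiply-accumulates at 224×224 (one MAC per convolution/linear product;
pooling, activations and batch-norm excluded); the canonical 1000-class
teacher counts 70,201,544, more than three times the student.

Training follows a two-phase schedule: joint minimisation of
`w·T²·KL(p_T ‖ q_T) + (1−w)·CE` (softened distributions at temperature
`T`), then a plain cross-entropy fine-tune. Defaults `T = 4` and
`w = 0.5` are conventional distillation settings — the KL/CE structure is
what matters, not these particular values — and both are configurable.
Augmentation applies horizontal flip, vertical flip and polar rotation —
a rotation about the fan apex, our reading of sector-preserving rotation —
each independently with probability 0.5, the angle uniform in ±15°.

Two desk-scale choices matter. First, the full teacher is always
countable, but training benchmarks substitute a width-reduced
split-attention proxy teacher (the identical code path at width 8 with one
block per stage), because training a 70 M-parameter network on one CPU is
not informative. Second, the phantom benchmark trains a width-8 ResNet-34
at 64×64 — the same topology, narrower — on 5×200 training and 5×50
validation frames for 6 distillation plus 2 fine-tune epochs.

## Stage 2a: dense dual-attention U-Net

The segmentor is an encoder–decoder with skip connections; four ablation
variants are built from the same skeleton: `plain_unet`, `unet_dense`,
`unet_dual_attention` and `dense_dual_attention`. Dense blocks augment
encoder levels 2–4 with 2, 4 and 8 dense layers (each layer sees the
concatenation of the level output and all previous dense layers and adds
`growth` channels; a 1×1 transition restores the level width). Because
the blocks augment rather than replace the level convolutions, every
dense variant is a strict layer superset of the plain U-Net. The dual-attention block at the
bottleneck runs two branches in parallel on the same features and fuses
them by addition: the position branch re-weights each location by a
softmax over query–key affinities of all locations (1×1 projections at
1/8 channel width); the channel branch re-weights each channel by a
softmax over the channel Gram matrix. Each branch adds its attended
features through a learnable gate initialised at 0.1, so the block starts
near the identity. Placement at the bottleneck only (configurable) keeps
the quadratic spatial cost bounded.

Full-scale defaults are five encoder levels at base width 64 with growth
32 and bilinear-equivalent (nearest ×2) decoder upsampling; the phantom
benchmark uses depth 4, width 8, growth 8 at 64×64. The loss is per-pixel
cross-entropy plus multi-class soft Dice, the common default for
imbalanced anatomy masks. Default classes are background/LA/RA; a 5-class mode adds
LV/RV as optional supervision, since four-chamber views contain
ventricles but refinement only consumes the atria.

On the frozen benchmark (200 training frames across the four target
views, 20 epochs) held-out mean atrium Dice exceeds 0.95. The ablation
benchmark (32 training frames, 8 epochs at batch size 4, seeds 1–3)
checks that the full variant is no worse than the plain U-Net in mean
Dice across seeds (within 0.02) and that every variant converges to a
useful segmentation. At this problem size the seed-to-seed spread is far
larger than the architecture effect, so a strict per-seed winner ordering
is not resolvable and is not asserted; resolving it would need training
runs orders of magnitude longer.

## Stage 2b: anchor-free candidate detection

The detector follows the FCOS design: a residual backbone, an FPN neck
(P3–P5 by default, strides 8/16/32, P6/P7 available), and heads shared
across levels predicting per-location classification, centerness and
four box distances (l, t, r, b). Distances are produced as
`exp(s_l · x) · stride` with a learnable per-level scale, hence
non-negative by construction. A location is a positive for a box when it
lies inside the box and `max(l,t,r,b)` falls in the level's size range —
(0,64] for P3, (64,128] for P4, (128,256] for P5 in input pixels — with
smallest-area tie-breaking; this sends small jets to high-resolution maps
and large ones to coarse maps. The loss is focal classification over all
locations plus IoU regression and binary-cross-entropy centerness over
positives, normalised by the positive count; the classification bias is
initialised to the focal prior (1 % foreground). Decoding multiplies the
classification and centerness sigmoids, thresholds at 0.05, and applies
greedy NMS at IoU 0.5. The clinical 0.95 cut-off is deliberately *not*
applied here so downstream ROC sweeps remain possible.

A clinical-scale detector operates at far larger compute than a desk CPU,
so the default backbone is width-8 with a 16-channel FPN; the benchmark
trains on 300 positive phantoms at 96×96 with jets of 24×14 px (jets much
smaller than the P3 stride contain no assignable location, which is a
property of the assignment rule, not a bug) and reaches frame-level
recall ≥ 0.8 at IoU 0.3 on 50 held-out positives.

## Stage 3: septum geometry and calls

`convex_hull_mask()` computes the hull of foreground pixel centers
(half-integer coordinates, so all boundary tests are exact in doubles)
and rasterises by center-in-polygon with boundary pixels included;
degenerate (collinear) hulls reduce to exact segment rasterisation.
`extract_septum()` subtracts the atria from the hull and dilates with a
disc structuring element (EBImage brush), default radius 5 px at 256×256,
scaling linearly with image size. A frame whose mask lacks either atrium
raises an error naming the missing chamber; the pipeline treats this as a
segmentation failure — the frame is flagged and its candidates pass
through unrefined, because silently discarding them would hide exactly
the failure mode that produces downstream false positives.

`filter_candidates()` keeps boxes whose septum overlap covers at least
`min_overlap_frac` (default 0.2) of the box area, measured by pixel
centers. "Outside the septum" is not by itself an operational criterion,
so we use a permissive fractional rule that approximates "any meaningful
overlap" while staying tunable. Image calls are positive iff the best refined
confidence is ≥ 0.95 (ties classified positive, matching the "greater
than or equal" operating rule); an image with no candidates is negative.
Case calls apply a 0.6 threshold to the *fraction of positive image
calls*; aggregating a case-level confidence instead would be an equally
defensible reading of a case threshold, so the interpretation is
configurable rather than hard-wired.

## Evaluation

Confusion-matrix metrics are the exact closed forms; a metric with a zero
denominator is reported `NA`, never 0. ROC curves sweep thresholds over
the unique scores with the ≥ convention, integrate by trapezoid (the AUC
then equals Mann–Whitney pair counting, which the tests verify on 1,000
random instances), and the Youden cut-point maximises
sensitivity + specificity − 1 with ties toward the higher threshold.
Confidence intervals use the Wilson score form, and before/after
refinement comparisons offer both McNemar's test (appropriate for paired
binary calls) and a paired t-test, since both conventions appear in the
clinical literature; neither is treated as a benchmark surface.

## The phantom generator

The generator emulates exactly the features the pipeline consumes: a
bright fan sector (apex top-center, half-angle 30°, radius 0.75 of the
frame — sized so ±15° apex rotations lose only interpolation pixels, not
clipped area), dark elliptical chambers with view-specific layouts
(subAS: atria side by side; A4C: four chambers, atria below; LPS4C: the
A4C layout tilted ≈25°; sax_basal: circular LA with an RA crescent;
"other": unlabeled distractor blobs), a septum gap of configurable
thickness, multiplicative Gaussian speckle, and pure-channel-saturated
red/blue jets centered on the septum midline with tight ground-truth
boxes. Geometric jitter is clamped at ±2 standard deviations so chamber
non-overlap holds by construction; a frame is bit-identical given its
spec and seed. Dataset generation allocates view counts exactly (floor
plus largest-remainder) and assigns exactly `floor(n·rate)` positives by
a seeded shuffle over septum-bearing views — "other" frames cannot be
positive because a jet requires a septum, which is why positives are
drawn from the four target views only.

What the phantoms do *not* model: beamforming physics, attenuation,
shadowing, motion blur, temporal cardiac cycles, anatomical variability
beyond affine jitter, and flow aliasing. Passing benchmarks therefore
demonstrates that the implementation learns and composes correctly, not
clinical performance; validating against clinical data requires a
hospital dataset and is out of scope. DICOM ingestion is likewise
omitted; the pipeline reads PNG/JPEG frames split from video upstream.

## Numerical choices and limitations

The CNN engine computes in double precision with He initialisation, Adam
(1e-3 unless stated), batch-norm with momentum 0.1 and eps 1e-5, and
deterministic single-threaded kernels — fixed seeds reproduce runs
bit-for-bit. Benchmark problem sizes (64–96 px frames, widths 8–16,
6–20 epochs) were chosen once as the smallest sizes at which each stage's
behaviour is clearly measurable on a single CPU. Softmaxes subtract the
row maximum; losses clamp probabilities at 1e-12; the IoU loss uses
subgradients at `min()` ties. Argmax ties in classification and
segmentation resolve to the lowest class code. The hull rasterisation and
box/pixel overlap rules use half-open boxes on a 0-based pixel grid with
pixel centers at half-integers throughout, so geometric unit tests are
exact rather than tolerance-based.
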