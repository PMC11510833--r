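---
title: "Extended-vision detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-vision detection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes: the
detector family and its assumptions, the parameters that matter and why
their defaults are what they are, what the synthetic scenes do and do not
emulate, and the numerical conventions behind the reported numbers.

## The detector family

All models share one skeleton: a convolutional backbone that halves
resolution five (or six) times, a path-aggregation neck that fuses
top-down and bottom-up across pyramid levels, and a decoupled anchor-free
head. Every convolution is bias-free with per-channel batch
normalization (trainable scale and shift; running statistics are
buffers) and SiLU activation, except where stated otherwise. The C2f
block splits a 1×1-expanded hidden map in two, chains `n` residual
bottlenecks on one half and fuses the split plus every intermediate
output; the C2 block is its cheaper sibling that concatenates only the
two halves. SPPF emulates 5/9/13 pyramid pooling with three cascaded
5×5 stride-1 max pools — an identity the test suite asserts exactly.

The head predicts, per grid cell and pyramid level, independent class
logits and a discrete distribution over `reg_max = 16` bins for each of
the four box sides (distances from the cell center in stride units);
boxes decode as the distribution expectation. `reg_max = 16`, hidden
bottleneck ratio 1.0 inside C2f/C2, split ratio 0.5, and the head widths
`c_box = max(16, ch/4, 64)`, `c_cls = max(ch, min(nc, 100))` are the
family's standard values; with depth/width multiples (0.33, 0.25),
(0.33, 0.50), (0.67, 0.75) for n/s/m and a width cap of 1024 channels
(768 at m scale — the cap the published m-scale size implies), the
assembled baselines reproduce the family's published parameter counts
exactly, which is the package's structural anchor.

### The three extensions

**MGEFA.** Each augmented backbone stage appends a multi-branch
group-enhanced fusion attention block: a 1×1 and a 3×3 branch, both
depthwise (group count = channels), each with batch norm + ReLU, each
gated by LSE — adaptive average pooling to a `g × g` grid (`g = 4`), a
1-D convolution of span 3 along the channel axis of every pooled cell, a
sigmoid, and nearest-neighbour broadcast back. Branch outputs are summed
and added to the input residually, so a zero-weighted MGEFA is exactly
the identity. Two placement/form decisions were genuinely open:

* *Branch groups.* Depthwise branches are the only form whose parameter
  cost (14 scalars per channel plus the 4-scalar LSE filters) keeps the
  s-scale integration below 0.01 M — the regime in which the published
  ablation reports an unchanged one-decimal parameter count. Grouped
  variants are available through `branch_specs`.
* *Placement.* Attention attaches to every backbone stage that exports a
  pyramid feature to the neck **except the deepest one**, which feeds the
  (optionally LSKA-augmented) pooling block and therefore already
  receives attention there. That is P3/P4 in the three-level model and
  P3/P4/P5 with P6 enabled.

**LSKA pooling.** SPPF_LSKA inserts large separable kernel attention on
the 4-way concatenated pooling pyramid before the final fusion: an
effective 11×11 depthwise receptive field factored into 1×3 and 3×1
local convolutions plus 1×5 and 5×1 dilation-2 convolutions, then a 1×1
channel mix, used multiplicatively. All five projections are bias-free:
an attention map feeds a multiplicative gate whose constant offsets are
absorbed by the normalization of the following fusion convolution, and
the bias-free form is what keeps the s-scale cost at the ~1.07 M
parameters the ablation's printed sizes imply. `K = 11` itself is a
calibrated choice — the effective field is not fixed by the published
description of this family — and is exposed as `lska_k`.

**P6.** The extended backbone inserts a stride-32 stage at base width
768 and a stride-64 stage at base width 1024 (the family's standard P6
trunk), pools at stride 64, and builds a four-level neck entirely from
C2 blocks: at these resolutions feature maps are deep but tiny, and the
dense intermediate reuse of C2f buys little for its cost. The head gains
a fourth scale at stride 64.

One reporting note: assembling the published ablation grid shows its
baseline rows agree with this package's exact counts under *truncation*
to one decimal, while the combined rows agree under rounding; no single
architecture reproduces every row to ±0.05 M (the attention deltas the
rows imply are mutually inconsistent — an ~0.005 M MGEFA cannot
simultaneously account for a 0.1 M step elsewhere). The package reports
standard rounding and documents the two rows it cannot reconcile rather
than distorting the architecture to chase them. GFLOPs behave similarly:
the all-components variant honestly profiles at ~28.7 G at 640², not the
lower figure its source row prints, which is inconsistent with the same
table's own single-component rows.

### Wise-IoU

The box loss follows the v3 form of the dynamic non-monotonic focusing
mechanism. With `L_IoU = 1 − IoU`, center distance `d` and enclosing-box
diagonal `c`:

* base term `exp(d²/c²) · L_IoU`, the denominator `c²` detached from the
  gradient;
* outlier degree `β = L*_IoU / m`, both factors detached, with `m` an
  exponential moving average of the batch IoU loss
  (`m ← momentum · m + (1 − momentum) · mean(L_IoU)`,
  `momentum = 1 − 1/2000`, updated only on training steps);
* gain `r = β / (δ · α^(β−δ))` with `α = 1.9`, `δ = 3`.

`r` vanishes for both very good (`β → 0`) and very poor (`β → ∞`) boxes
and has a single interior maximum — asserted by a numeric sweep — so
training concentrates on boxes of middling quality. The gradient
detachment contract is tested against a finite-difference oracle that
holds the detached quantities constant. The running mean starts at 1
(the ceiling of the IoU loss, the scale expected early in training); a
zero mean engages a warmup guard `β := 1`. Whether the original experiments
retuned α/δ is unknown; they are exposed as hyper-parameters, not
treated as facts.

Training pairs Wise-IoU with task-aligned assignment (top-10 anchors per
target by `score^0.5 · IoU^6` among anchors whose center lies inside the
box), binary cross-entropy on the aligned soft scores, and a
distribution-focal term on the two bins bracketing each true distance,
weighted 7.5 : 0.5 : 1.5 (box : cls : dfl) — the family's defaults; the
published description is silent on all three. One deliberate deviation from
the reference assigner: a target containing **no** anchor center (possible
for sub-resolution boxes) falls back to the nearest anchor in stride
units, and zero-metric fallback assignments receive a small positive
target score (0.25), so every annotated object trains at least one
anchor instead of silently dropping out of the loss.

## The array engine

No deep-learning framework is assumed: the package carries a small
reverse-mode engine over `(C, H, W, N)` arrays. Dense convolutions run
as one BLAS matmul per kernel tap against shifted slices of the padded
input (identical FLOPs to im2col without materializing the k²-fold
column matrix); depthwise convolutions broadcast per-channel taps by
vector recycling; every operator's backward pass is checked against
central finite differences in the test suite. Max-pool gradient ties
are split among all attaining positions (they occur only on constant
inputs); batch norm uses ε = 1e-5 and running-statistic momentum 0.1,
with batch statistics in training mode and buffers at inference.
Optimization is plain SGD (momentum 0.937, weight decay 5e-4 on
convolution kernels only, per-element gradient clipping at 10), with a
10-step linear warmup and linear decay to 1% of `lr0 = 0.01` — the
initial rate and optimizer are the published training configuration;
the schedule shape follows the reference implementation's defaults.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` paints a textured soil background (low-frequency
bilinear noise plus darker foliage ellipses) and 2–5 lobed plant blobs
per 64 px scene. Class identity controls lobe count and hue; size is
log-uniform in 0.16–0.35 of the image edge; with probability 0.3 an
object is placed overlapping an earlier one, and labels always record
each blob's own painted extent *before* later paints cover it — so
occluded objects carry full-extent boxes, as in real annotation
practice. Scenes are exactly reproducible from their seed and quantized
to the 8-bit grid so PNG round trips are bit-exact.

The size range is an emulation-design decision worth stating: the
smallest objects span ≥1.3 cells of the finest (stride-8) detection
grid. Field weed imagery that this generator stands in for is detected
at 88–96% mAP@0.5 by this model family, which implies its objects are
predominantly resolvable at the detector's finest stride; an earlier
draft of the generator produced sub-cell (6–9 px) objects, a regime in
which *no* member of this architecture family can localize at IoU 0.5
and which therefore tests the emulation, not the method. The range
remains a parameter, so the sub-resolution regime is one line away.

What passing tests on these scenes do **not** show: robustness to real
lighting, blur, viewpoint and growth-stage variation; crop–weed look-alike
confusion (classes here differ by hue and lobe count); annotation noise;
and any claim about accuracy on the real datasets the generator imitates
— reproducing those numbers requires full-scale GPU training, which is
out of scope. The desk-scale claim the suite does establish is
end-to-end trainability: the full extended-vision pipeline (assignment,
Wise-IoU, distributional decoding, attention blocks) overfits 16 scenes
to mAP@0.5 ≥ 0.9 within 200 full-precision SGD steps on one CPU core.

Augmentation implements the published recipe — random crop/zoom,
horizontal/vertical flips, brightness/contrast/saturation/hue jitter —
with magnitudes as documented defaults (not asserted facts); boxes
survive a crop only if at least 2 px a side and 25% of their original
area remain. Mosaic composition is deliberately excluded; the recipe in
the source material lists crop/scale/flip/colour only.

## Numerical conventions

* **Parameter counts** are exact integer counts of trainable scalars of
  the assembled arrays (normalization scale/shift included; running
  statistics and the fixed bin-projection excluded), reported as
  millions at one decimal. An independent closed-form per-layer
  summation reproduces every count in the tests.
* **FLOPs**: 2 per multiply–accumulate, batch 1, normalization fused;
  pooling and elementwise terms are counted at one FLOP per produced
  element (k² for max pools) and sit two orders of magnitude below the
  convolution term. 640 × 640 is the profiling size under which the
  published baseline figure is reproduced.
* **Metrics**: precision/recall return 0 with a warning at zero
  denominators; AP uses the all-point interpolated envelope (a 101-point
  COCO-style mode exists for cross-checks); confidence ties keep input
  order; matching is per class with greedy consumption in confidence
  order; classes without ground truths are excluded from the mean with a
  warning; degenerate zero-area boxes overlap nothing by convention.
* **Problem sizes in the suite**: 64 px scenes, 16-image overfit runs of
  200 steps at batch 8, and n-scale models for everything dynamic;
  structural checks build the full n/s/m grid at 640. These sizes are
  the package's desk-scale choices and keep the complete suite in the
  minutes range on a single core.

## Known limitations

* CPU-only and R-native: throughput is desk-scale (seconds per training
  step at 64 px); there is no AMP, EMA, mosaic scheduling, multi-GPU or
  export path, and no attempt to reproduce published accuracy or FPS.
* Batch-norm statistics at batch 8–16 are noisy; evaluation uses running
  buffers warmed during the short runs.
* The assigner is the task-aligned scheme only; alternative matchers are
  out of scope.
* Checkpoints are RDS files tied to this package's configuration schema
  (versioned, but not an interchange format).
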