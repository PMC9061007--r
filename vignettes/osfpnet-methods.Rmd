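---
title: "Four-path object-specific pooling networks for carotid plaque classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-path object-specific pooling networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The classification problem

Subjects with carotid atherosclerotic plaque are imaged bilaterally with
B-mode ultrasound in two orthogonal planes, yielding four plaque regions of
interest per subject: left and right artery, each in transverse (near-square)
and longitudinal (elongated) section. The task is subject-level binary
classification — symptomatic (a prior TIA or ischemic stroke; the positive
class) versus asymptomatic — from those four grayscale ROIs alone. Two
properties of the data drive the architecture:

* ROIs have **arbitrary pixel dimensions**; resizing them to a common shape
  would distort the very texture and scale cues that carry risk information.
* The two sections have **different geometry**: transverse plaque ROIs are
  roughly square, longitudinal ROIs are long strips, so a single pooling
  scheme serves neither well.

## Model

The network has four parallel paths, one per view, in fixed order LT, LL,
RT, RL. Each path is a feature-extraction stage (FE) followed by an
object-specific feature-downsampling stage (FD).

**FE.** The convolutional stage of VGG16: five blocks of (2, 2, 3, 3, 3)
3×3 convolutions (stride 1, padding 1, ReLU) with (64, 128, 256, 512, 512)
channels, a 2×2 stride-2 max pool after each block *except the last*. An
H×W input therefore yields k = 512 feature maps of size ⌊H/16⌋×⌊W/16⌋ —
any input size is accepted and none is resized. The four FEs share one
architecture; their weights are independent by default (`tie_fe_weights`
shares them), since nothing requires the left and right arteries to be
encoded identically.

**FD.** Both FD types partition a feature map into adaptive grids whose bin
boundaries along an axis of extent `e` split into `n` bins as
`[floor(i·e/n), ceil((i+1)·e/n))` (0-based, half-open; bins may overlap by
one cell when `e` is not a multiple of `n`, and jointly always cover the
axis — `adaptive_bin_edges()`):

* **SPP** (transverse paths 1 and 3): square pyramid levels 1×1, 2×2, 3×3 —
  14 bins per channel, max-reduced, giving a 14k-vector.
* **MSP** (longitudinal paths 2 and 4): strip levels 1×1, 2×1, 3×1, read as
  divisions along the map *height* with each strip spanning the full width,
  so a strip aggregates long-range horizontal context along the vessel
  axis — 6 strips per channel, average-reduced, giving a 6k-vector.

The descriptor length is `k·Σ aₙ·bₙ` for any input size. Reduction
operators: max is the classical choice for pyramid pooling and average for
strip pooling; both are configurable (`pooling_spec(operator=)`). The axis
convention for strips ("aₙ×1") and the operators are design choices on
points the architecture description leaves open; they are documented here
rather than asserted as the only possible reading.

The four descriptors are concatenated (2·14k + 2·6k = 40k entries; 20480 at
k = 512) and classified by fully connected layers (4096, 4096, 2) with
dropout before the last layer. Dropout follows the Bernoulli-mask
formulation with retention probability p (drop probability 0.5 by default,
the canonical value); we use *inverted* dropout — the kept activations are
scaled by 1/p at training time — so inference applies no rescaling and is
deterministic. Class index 1 = symptomatic = positive throughout.

## Training protocol

Cross-entropy loss, SGD with momentum 0.9, initial learning rate 0.001
divided by 10 after every 6 epochs, 30 epochs, batch size 1. Batch size 1 is
forced by the data contract, not preference: quadruples from different
subjects have different pixel dimensions and are never padded or resized, so
they cannot be stacked into one tensor. "Iterations" in the protocol are
read as epochs: 30 single steps with a decay every 6 would be degenerate,
while 30 epochs matches the schedule's intent. No weight decay is used.

Two numerical choices stabilize *training from scratch*, and both are
confined to initialization and step control rather than the architecture:

* **Data-dependent initialization** (`standardize_init`, default on): hidden
  layers are He-initialized and the final scoring layer starts at zero; then
  the per-feature mean and spread of the concatenated descriptor over the
  *training* subjects is folded into the first FC layer's initial weights
  (W ← W/s, b ← b − W·m/s, with the scale floored at its median so weak
  features are never amplified). Max/average-pooled ReLU descriptors are all
  positive with a large common mode; without centering, early batch-1
  gradients point almost entirely along that common mode and training
  plateaus at the class prior. Folding the standardization into the starting
  point leaves the reachable function class unchanged — it is an
  initialization, not a layer — and is computed per training split, so
  cross-validation test folds never contribute.
* **Gradient-norm clipping** (`clip_grad_norm`, default 5): single-subject
  steps occasionally produce very large gradients which momentum then
  amplifies into divergence; clipping bounds the global step norm without
  changing its direction.

When a pretrained VGG16 convolutional checkpoint is supplied
(`build_backbone(..., checkpoint=)`, grayscale replicated to 3 channels),
neither device is needed; no checkpoint ships with the package, so the
default path is seeded random initialization.

## Patient-level cross-validation

`make_folds()` implements the K5 protocol (80% train / 20% test per round)
at the *patient* level: five fold sizes are drawn within a band — [65, 70]
for 333 subjects, scaled proportionally (`round(65n/333)` to
`round(70n/333)`) otherwise — until they sum to n, then shuffled subjects
fill the folds. A draw for 333 subjects gives sizes such as 66, 66, 66, 66,
69, so holding out a 66-subject fold trains on 267 subjects. If the band is
infeasible the split falls back to near-equal sizes with a warning.

Augmentation (below) is applied strictly *after* the split and only to the
training side; a guard compares source subject IDs (augmentation suffixes
stripped) and aborts on any overlap, so no variant of a test subject can
leak into training. Per fold, the epoch checkpoint with the highest held-out
accuracy is retained; note this selection uses the test fold itself (there
is no nested validation split in the protocol), so the "best" weights are
optimistically selected and the primary metrics are the per-fold test
metrics averaged over folds.

## Augmentation

Seven variants per subject: the original, rescalings by 0.8, 0.9, 1.1 and
1.2 (bilinear, output sizes rounded), and a horizontal and a vertical flip.
All four views of a subject receive the same transform and keep their label,
and flips are applied subject-consistently (whether per-image or per-subject
flipping was intended is not stated; per-subject is the conservative
reading). 333 subjects / 1332 images thus become 2331 subject variants /
9324 images. A 0.8× rescale requires source sides of at least
⌈48/0.8⌉ = 60 px to respect the minimum input size; the generator's default
minimum of 48 px is therefore incompatible with the full recipe, and
augmentation raises an error naming the subject rather than silently
dropping or padding. Cohorts intended for augmentation should be generated
with 60 px minima (as the package's own augmentation checks do).

## Synthetic cohort

No clinical images ship with the package, so a generator
(`generate_cohort()`) emulates the *structural* properties the network
relies on: four views per subject; transverse sides uniform on 48–160 px
with width/height in [0.75, 1.33]; longitudinal heights uniform on 48–96 px
with aspect ratio uniform on 2.5–5; 8-bit grayscale. Texture is classical
fully developed speckle: a Gaussian-smoothed random echogenicity background
multiplied by Rayleigh noise with unit mean (B-mode speckle amplitude is
classically Rayleigh). The class effect enters as a mean-echogenicity
deficit (−0.08·`effect_size` on a 0.60 baseline) and a background-contrast
(heterogeneity) excess (×(1+0.75·`effect_size`)) for the symptomatic class,
reflecting the association of hypoechoic, heterogeneous plaque with risk;
the direction is an assumption, since class-conditional intensity statistics
of real cohorts are not characterized in the source material. The default
class imbalance is 117:216 (`symptomatic_fraction = 117/333`).

What the generator does **not** model: beamforming, attenuation, shadowing,
anatomy (vessel wall, lumen), inter-plaque correlation within a subject, or
any realistic relation between plaque morphology and outcome. Passing tests
on this cohort therefore demonstrate that the implementation is correct and
that the pipeline can learn a class-separable texture signal at desk scale —
not that the architecture attains any particular clinical accuracy.

## Desk-scale configuration and problem sizes

The full-width network (k = 512, FC 4096) exists and type-checks shapes
(`classifier_input_length(osfp_config())` is 20480; the default backbone has
the 14,714,688 convolutional parameters of VGG16 when configured with
3-channel input), but training it on a CPU is impractical. The package's
working configuration for tests and examples is `osfp_config_tiny()`: the
same depth at 1/8 width (k = 64, FC 256), identical contracts. The test
suite trains it on a 40-subject synthetic cohort with a large class effect
(`effect_size = 2`) and desk-scale ROI ranges (transverse 48–96 px,
longitudinal height 48–64 px, aspect 2.5–3.5 — the same structure at
smaller pixel counts) under the training protocol with early stopping at 0.9
training accuracy, truncated at 12 epochs — a stricter subset of the
30-epoch budget, since the schedule's learning rate is at most 1e-5 from
epoch 12 on — and runs the no-signal null check (`effect_size = 0`)
as a 5-fold cross-validation at 2 epochs per fold — enough optimization to
expose leakage, which is what a null check is for, while staying within a
few CPU-minutes.

## Degenerate inputs and edge policies

* Metrics with zero denominators (e.g. precision with no predicted
  positives) are reported as `NA` with an `undefined` flag, never as 0, so
  fold averages are not silently deflated.
* A paired t-test on a zero-variance difference series is flagged
  `degenerate` with an `NA` p-value instead of a fabricated one.
* ROC/AUC requires both classes present and refuses otherwise.
* Feature maps smaller than the finest pooling grid, inputs below 48 px,
  non-binary labels, missing manifest files and unknown configuration keys
  all fail loudly with the offending name in the message.

## Known limitations

* Training from random initialization on tens of subjects is far from the
  pretrained fine-tuning regime the architecture was designed for; the
  stabilizers above make it reliable but per-seed variation remains, and the
  protocol's late epochs (learning rate ≤ 1e-5) contribute little.
* The Rayleigh-speckle cohort is a structural stand-in; no clinical claim
  transfers from it.
* The pretrained path is a hook: checkpoint loading is shape-validated, but
  producing such a checkpoint requires an external source of ILSVRC-trained
  VGG16 convolutional weights.
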