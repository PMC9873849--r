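---
title: "Weakly-supervised lesion localization with multi-resolution CAMs and pixel-correlation refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised lesion localization with multi-resolution CAMs and pixel-correlation refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chest radiographs are labelled at the image level — a study is tagged with
the findings it contains, but almost never with where they are. Drawing
boxes requires an expert, so in datasets like NIH ChestX-ray14 only about
1,000 of 112,120 images carry box annotations. Weakly-supervised
localization trains a multi-label classifier on the image-level tags alone
and extracts localization from its class activation maps (CAMs): apply the
classification weights at every location of the final feature map instead
of after global pooling, and the resulting per-class map marks the evidence
the classifier used.

Two known failure modes motivate the two architectural additions this
package implements. First, a standard stride-32 CNN leaves a 256-pixel
input with an 8×8 CAM; upsampled ×32, its activations often miss the
abnormality entirely. Second, CAMs systematically under-activate (they
cover only the most discriminative fragment) and over-activate into
background. The remedies are, respectively, a **multi-resolution backbone**
that re-fuses early high-resolution features into the coarse output, and a
**pixel correlation module (PCM)** that rewrites each CAM pixel as a
feature-similarity-weighted average of all CAM pixels, trained with a
self-supervised equivariance objective (SEAM).

```{r setup}
library(camloc)
```

## Model

### Multi-resolution backbone

A staged CNN produces raw features $F^l$ at resolution levels
$l = 2,\dots,5$ (level $l$ has stride $2^l$, so a 256-input yields an 8×8
map at level 5). Resolution-preserving features are built coarse-to-fine by
the recursion

$$F_o^5 = F^5, \qquad F_o^l = g\!\left(F_o^{l+1},\, F^l\right),$$

where the merge block $g$ (i) reduces the channels of both inputs by a
factor of 4 with 1×1 convolutions followed by ReLU, (ii) bilinearly
upsamples the coarse input ×2, (iii) concatenates, and (iv) projects back
to $F^l$'s channel count with a final 1×1 convolution + ReLU. The output of
$g$ has exactly $F^l$'s shape, which is what makes the recursion well
defined; merging down to level 2 yields a CAM 8× finer per side than the
standard model.

Three bases are available. `"tiny"` is a width-reduced 4-stage CNN (8–64
channels) whose weights are instantiated and trainable on a CPU; it exists
so that the full pipeline — training included — runs at desk scale.
`"resnet50"` and `"efficientnet_b4"` are exact layer inventories: every
parameter tensor of the standard torchvision constructions is enumerated
(convolutions without biases, batch-norm scale and shift as parameters,
running statistics as buffers), so `count_parameters()` reproduces the
published budgets exactly:

```{r}
count_parameters(assemble_multires_model("resnet50", 14, multires = FALSE))
count_parameters(assemble_multires_model("efficientnet_b4", 14, multires = FALSE))
```

The finest merged level is a configuration knob (default 2). The published
parameter counts of the *multi-resolution* variants cannot be reconstructed
from the description of the blocks, so the multi-resolution inventories
here follow this package's own merge-block definition and are not claimed
to match any published number.

### Classification head and CAMs

A single affine classifier $(W, b)$ shared across pixels scores every
location of the output feature map, giving one CAM per class,
$\widehat{y}_c(i,j) = W_c^\top F_o(i,j) + b_c$. The class score is the
log-sum-exp (LSE) pool of that same map:

$$z_c = \frac{1}{\gamma}\,\log\!\Big(\tfrac{1}{hw}\sum_{ij} e^{\gamma\,\widehat{y}_c(i,j)}\Big),$$

a smooth interpolation between mean pooling ($\gamma \to 0$) and max
pooling ($\gamma \to \infty$), computed with a max shift for overflow
safety; $\gamma = 10$ throughout. Scoring per pixel and *then* pooling (as
opposed to pooling features first) makes the identity
$z_c = \mathrm{lse}(\widehat{y}_c)$ exact, so the CAM really is the spatial
decomposition of the score the classifier produced — the package asserts
this identity on random instances in its test suite.

Before PCM refinement, non-maximum activations are suppressed: at each
pixel only the class with the maximal activation keeps its value, ties
going to the lowest class index, and a kept value that is negative is
clamped to zero. The clamp encodes "a pixel whose best class is negative
carries no foreground" and is what makes suppression idempotent — without
it, a pixel whose kept value is negative would flip to an introduced zero
on a second application.

### Pixel correlation module

Let $x_i$ be the backbone feature vector at pixel $i$ (interpolated to the
CAM grid if needed) and $\theta$ a learned linear embedding (a 1×1
convolution with no non-linearity — the module's only trainable part). The
refined CAM is

$$y_i = \frac{1}{C(x_i)} \sum_j \mathrm{ReLU}\!\left(\cos(\theta x_i,\,\theta x_j)\right)\widehat{y}_j,
\qquad C(x_i) = \sum_j \mathrm{ReLU}\!\left(\cos(\theta x_i, \theta x_j)\right).$$

Defining the normalizer as the row sum of the clipped cosines is the only
reading under which refinement is exactly a convex combination — each
refined pixel lies within the original CAM's range, and every affinity row
sums to one (self-similarity is 1, so rows always have positive mass).
Embedded vectors with norm below $\varepsilon = 10^{-8}$ get an identity
row: such pixels keep their own value.

Two PCM choices were genuinely open and are worth recording:

* **Feature source.** The embedding consumes the final
  resolution-preserving map $F_o^{\text{finest}}$ (single map, the default;
  configurable). The SEAM lineage concatenates several feature levels; with
  the single-map choice the behaviour is equivalent up to the embedding's
  input width.
* **Embedding width.** The default is $C_e = C_{in}/4$. On the tiny base
  this default collapses: post-ReLU CNN features share a dominant
  nonnegative direction, so pairwise cosines start near 1 and a 2-channel
  embedding of 8-channel features yields an affinity matrix numerically
  indistinguishable from uniform (mean row entropy 5.545 vs
  $\log 256 = 5.545$ on a 16×16 grid) — refinement then degrades into a
  global average. The tiny preset therefore embeds at full width
  ($C_e = C_{in} = 8$) and lets $\theta$ learn the anisotropy. For wide
  backbones (512+ channels) the /4 reduction is unproblematic.

## Losses

### Dynamically class-balanced BCE (phase 1)

Thoracic findings are rare per class, so an unweighted BCE drives the model
to the constant-negative solution. Per batch and class $c$, with $|P_c|$
positive and $|N_c|$ negative samples,

$$\beta_P^c = \frac{|P_c|+|N_c|}{|P_c|}, \qquad
  \beta_N^c = \frac{|P_c|+|N_c|}{|N_c|},$$

and the loss is
$\sum_c -\beta_P^c\, y_c \log f_c - \beta_N^c (1-y_c) \log(1-f_c)$. The
weights are recomputed every batch and satisfy
$1/\beta_P^c + 1/\beta_N^c = 1$ whenever both counts are positive. When a
class has no positives in a batch its positive term vanishes anyway, so
$\beta_P^c$ is set to 0 (symmetrically for no negatives). The published
form is a per-sample class sum; this package averages that sum over the
batch so the learning rate is invariant to batch size. Probabilities are
clamped to $[10^{-7}, 1-10^{-7}]$ inside the logarithms.

### Siamese PCM objective (phase 2)

CAMs should be *equivariant* under spatial transforms: transforming the
input and then mapping should equal mapping and then transforming. The PCM
is trained to close the gap between the two orders with a weight-shared
Siamese pass — one branch feeds the rotated image through the network, the
other rotates the network's output — and the equivariant cross
regularization (ECR) couples raw and refined CAMs *across* branches:

$$\mathcal{L}_{ECR} = \big\|A(y^o) - \widehat{y}^t\big\|_1 + \big\|A(\widehat{y}^o) - y^t\big\|_1 .$$

The ECR appears in the literature both with a plus and (likely a
typographical slip) a minus between the two norms; a difference of
absolute values is unbounded below and contradicts the construction ECR
derives from, so this package uses the sum. Online hard example mining (OHEM) keeps, per term, only
the largest 20% of the per-pixel-per-class losses
($\lceil 0.2\,N\rceil$ elements, averaged); pixels invalidated by the
rotation (the rotated-in border) are masked out before selection. Whether
OHEM pools the two terms jointly was unstated; this package reduces each
term separately and adds the reductions.

As an additional supervision source, the refined CAMs of both branches are
global-average-pooled into prediction vectors and scored against the
image-level labels with the multi-label soft-margin loss
$\;\mathrm{mean}\,[\,y\log(1+e^{-z}) + (1-y)\log(1+e^{z})\,]$, averaged
over the two branches (the combination rule across branches was unstated).
The total phase-2 objective is

$$\mathcal{L}_{PCM} = 1.5\,\mathcal{L}_{MSML} + 1.0\,\mathcal{L}_{ECR}.$$

## Training schedule

* **Phase 1** — backbone + classifier, Adam with betas $(0.9, 0.9)$,
  learning rate $3\times10^{-4}$, 35 epochs, micro-batch 32 with 3
  gradient-accumulation steps (effective batch 96; accumulated gradients
  are averaged, so accumulation is exactly equivalent to a larger batch on
  identical micro-batches — a property the tests verify on duplicated
  data). Optionally only later stages are trainable (the full-scale recipe
  freezes stages 1–2 of the pretrained base).
* **Phase 2** — PCM only; every other weight is frozen, which also
  guarantees the classification path is bit-identical before and after
  (refinement feeds only the localization path). Per image a rotation is
  drawn uniformly in $(-30°, +30°)$; flips are never sampled. Rotations of
  CAMs use the same bilinear interpolation and zero fill as for images, as
  an explicit sparse linear operator whose transpose is the exact adjoint
  used in backpropagation. The gradient of the objective with respect to
  $\theta$ is analytic (cosine-affinity backward pass) and is verified
  against central finite differences in the test suite.

The full-scale defaults live in `train_config()`. The desk-scale preset
`tiny_train_config()` adapts the schedule to a 200-image problem: phase 1
runs micro-batch 8 without accumulation at learning rate $3\times10^{-3}$
(≈25 updates per epoch, 5 epochs); phase 2 uses $10^{-2}$ for 3 epochs. The
phase-2 rate was chosen from optimization diagnostics: at $10^{-3}$ the
embedding moves ~3% of its norm over a whole run and the ECR loss is flat,
while at $10^{-2}$ the ECR decreases epoch over epoch and the affinity
entropy falls.

## Synthetic data

`generate_dataset()` renders the study's fixture world: square grayscale
images (default 64 px) containing class-discriminative geometric lesions —
a filled disk, a ring (annulus), and a bar — at configurable additive
intensity (defaults 0.45–0.50) and size (default box sides 10–16 px), over
a smooth low-frequency background (bilinear upsampling of coarse uniform
noise in [0.15, 0.45]) plus Gaussian pixel noise (sd 0.05). Roughly a
configurable fraction of images (default 20%) are disease-free; positive
images carry 1–3 classes with 1–2 lesions each. Every lesion is recorded as
a tight `(x, y, h, w)` box unless the image is drawn label-only, emulating
datasets where almost all images lack box annotations. Patients contribute
1–3 images each, and all splits are taken at the patient level.

What this emulates: the NIH directory dialect (PNG images, pipe-separated
finding labels with a `No Finding` sentinel, a bbox table in the protocol's
`(x, y, h, w)` order, patient-level split lists), multi-label structure,
class imbalance, and localized class-discriminative structure. What it does
not: anatomy, projection physics, inter-class co-occurrence statistics,
reader noise, or any radiographic appearance. A passing end-to-end run
demonstrates that the pipeline's machinery is correct and that its losses
and protocol compose as intended — not that the model would reach any
particular performance on real radiographs.

## Evaluation protocol

Each class CAM is bilinearly upsampled to the evaluation frame, min-max
normalized per map, and quantized to 0–255 (`round()`, half-to-even; a
constant map carries no signal and maps to zeros). The normalized scale is
what makes a constant threshold meaningful: the mask is `value > Q·255`
with $Q = 0.7$, its 8-connected components are labelled with a two-pass
union-find sweep, and each component's tight box is a predicted box.

Boxes are scored with **IoBB** — intersection area over *predicted*-box
area, so a predicted box fully inside the ground truth scores 1 regardless
of the ground truth's size. A ground-truth-annotated image counts as
correctly localized for class $c$ if at least one predicted box exceeds the
threshold, strictly: $\mathrm{IoBB} > T$, default $T = 0.1$. **Lacc** is
the fraction of such images; **FPN** is the number of predicted boxes
failing the threshold against every ground-truth box of their class,
divided by the number of evaluated images. Both restrict to images carrying
ground truth for the class (the false-positive scope on unannotated images
is left open by published protocol descriptions; the restriction matches how the
benchmark the protocol descends from averages). Predicted boxes are
produced in the model-input frame; against annotations at a different
resolution, `scale_boxes()` maps them by the known resize ratio (×4 for a
256-input against 1024-frame annotations). Classification is scored with
per-class trapezoidal ROC-AUC (midrank ties); single-valued classes are
reported absent rather than imputed.

Box coordinates are 0-based with the origin at top-left; boxes are closed
on the left/top edge and exclusive on the right/bottom edge. Published
protocol descriptions leave the convention open; this one makes `x + w <= width` the bounds
invariant.

## Desk-scale study and its limits

The end-to-end validation trains the tiny multi-resolution base
(finest level 2, so 16×16 CAMs on 64-pixel images) for 5 epochs on ~200
synthetic images (3 lesion classes) with ~50 held out at the patient level,
then trains the PCM for 3 epochs. At the study's fixed seeds this reaches a
held-out mean AUC above 0.9 and disk-class Lacc near 1; across other seeds
the 5-epoch mean AUC typically lands in 0.78–0.92 (individual class AUCs
swing more — a 200-image, 125-update run is genuinely init-sensitive), and
phase-2 PCM training leaves the classification path bit-identical while
improving or preserving refined-CAM localization. The problem sizes were
chosen so the whole suite runs in about a minute on one CPU core; they are
the package's validation scale, not a claim about convergence behaviour at
dataset scale.

Other known limitations: the parameter inventories for ResNet50 and
EfficientNetB4 are counting models, not runnable networks; rotations are
the only affine family implemented for the Siamese pass (flips are
deliberately excluded, reflections having shown no benefit); and the PCM embedding-width default is inappropriate
for very narrow backbones, as discussed above.

## Numerical choices, collected

| Quantity | Value | Where |
|---|---|---|
| LSE sharpness $\gamma$ | 10 | `lse_pool()` |
| Heatmap threshold $Q$ | 0.7 | `cam_to_boxes()` |
| IoBB threshold $T$ | 0.1 (strict `>`) | `localization_accuracy()` |
| OHEM keep fraction | 0.20, $\lceil f N\rceil$ kept | `ecr_with_ohem()` |
| Loss weights $(\lambda_{MSML}, \lambda_{ECR})$ | (1.5, 1.0) | `seam_loss_config()` |
| BCE probability clamp | $10^{-7}$ | `weighted_bce()` |
| PCM norm guard $\varepsilon$ | $10^{-8}$ | `embed_and_affinity()` |
| Quantization | `round()` to 0–255, half-to-even | `rescale_heatmap()` |
| Suppression ties | lowest class index; negative kept values clamped | `suppress_non_maximum()` |
| Upsampling | bilinear, half-pixel centers, no corner alignment | `resize_bilinear()` |
| Rotation fill | zeros; invalid pixels masked in ECR | `make_warp()` |
| Crop sampling | rejection sampling until the rounded area is in range | `augment_policy()` |

## A note on shape

The package's core objects are image tensors and CAM stacks, so the
numerical surface is array-in/array-out; everything tabular — label and box
tables, split assignments, loss histories, per-class metrics — flows
through tibbles, and fitted objects expose `tidy()`, `glance()` and
`autoplot()`.
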