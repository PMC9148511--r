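---
title: "Dilated convolutions for dermoscopic lesion segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilated convolutions for dermoscopic lesion segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilatedskinnet)
```

## The problem and the model

Dermoscopic images of skin lesions are segmented into two pixel classes,
*lesion* and *background*. The difficulty is not the classifier but the
nuisances: hairs crossing the lesion, gel bubbles, illumination gradients,
low contrast, and highly irregular borders. The network implemented here —
DilatedSkinNet — is a fully convolutional classifier with **no pooling and
no encoder–decoder**: every one of its 16 convolutional layers works at the
full input resolution (nominally $192 \times 256$), and spatial context is
gathered instead by *atrous (dilated) convolutions*, whose kernel taps are
spaced $r$ pixels apart:

$$C[i] = \sum_{s} I[i + s \cdot r]\, K[s], \qquad r \ge 1 .$$

A $3\times3$ kernel at rate $r$ has effective extent $k_\text{eff} = 3 +
2(r-1)$, so stacking rates $1,2,4,\dots,14$ grows the receptive field to
$1 + \sum_\ell (k_\text{eff}^{(\ell)}-1) = 179 \times 179$ pixels without
adding parameters. `receptive_field()` computes this closed form and
`empirical_receptive_field()` verifies it by backpropagating a one-hot
gradient from a single output pixel and measuring the support of the input
gradient; with batch statistics the batch-norm backward couples all pixels,
so the oracle is evaluated in inference mode, where batch norm is a fixed
per-channel affine.

Each convolution (except the final $1\times1$ classifier) is followed by
batch normalization and leakyReLU with slope $a = 0.1$:

$$\hat{x} = \frac{x - \mu_B}{\sqrt{\sigma_B^2 + \epsilon}}, \qquad
  y = \gamma \hat{x} + \beta, \qquad \epsilon = 5\times10^{-5},$$

with per-channel statistics taken over all pixels of the mini-batch. The
final $1\times1$ layer maps 128 features to 2 channels, and a pixel-wise
softmax yields class probabilities; the predicted mask is the argmax, with
exact $0.5/0.5$ ties resolved to background (a conservative, deterministic
convention).

```{r architecture}
spec <- dilatedskinnet_spec()
arch_report(spec)
count_parameters(spec)[c("conv_total", "bn_total", "total")]
receptive_field(spec)
```

The layer table is encoded as data (`dilatedskinnet_spec()`), so the
structural claims — all output sizes $192\times256$, the channel chain, the
dilation schedule — are checkable rather than implicit in code. Two details
are worth flagging:

* The $1\times1$ layers carry a dilation rate in the published table; a
  single tap has no spacing, so the rate is stored for fidelity but has no
  numerical effect, and it contributes nothing to the receptive field.
* The closed-form learnable-parameter count is $327{,}858$ convolution
  weights/biases plus $1{,}712$ batch-norm scales/offsets ($329{,}570$
  total, about $3.27\times10^5$). The package reports the computed value.

## Loss, optimizer, and the training recipe

Training minimizes the weighted cross-entropy over all pixels,

$$\mathcal{L} = \frac{1}{N} \sum_{n=1}^{N} \sum_{i=1}^{K}
   w_i\, T_{ni}\, \bigl(-\log P_{ni}\bigr),$$

with $K = 2$ and class weights $w$ set to inverse pixel frequency over the
training masks, normalized to mean 1 — the standard remedy for the
lesion/background imbalance. Probabilities are clamped to
$[10^{-12}, 1]$ before the logarithm so a saturated softmax cannot produce
an infinite loss. The optimizer is stochastic gradient descent with
classical momentum,

$$v \leftarrow \gamma_m v - \alpha\,(\nabla\mathcal{L} + \lambda\theta),
  \qquad \theta \leftarrow \theta + v,$$

which reduces to plain gradient descent at $\gamma_m = 0$. The recipe
(`train_config()` defaults): batch size 16, $\alpha = 0.01$,
$\gamma_m = 0.9$, $\lambda = 0.005$. The L2 term is applied to convolution
weights only, not to biases or batch-norm parameters — the convention of
the mainstream SGDM implementations this recipe comes from. Further
choices the recipe leaves open, fixed here:

* **Weight initialization**: variance scaling aware of the leakyReLU slope,
  $\mathrm{sd} = \sqrt{2 / ((1+a^2)\,k^2 C_\text{in})}$, with the seed
  exposed in `build_network()`.
* **Batch-norm statistics at inference**: running mean/variance accumulated
  with momentum 0.9 during training are frozen into the model and used for
  prediction.
* **Model selection**: the checkpoint with the best validation Jaccard
  index is returned; when no validation set is given, the training set is
  split 7:3 (seeded), the same ratio the source experiments used.
* **Epoch count**: not part of the published recipe; the default is 30.

The gradient path is hand-written (im2col gather + BLAS matrix products,
with the batch-norm backward using the population-statistics formula) and
is validated against central finite differences in the test suite; the
forward pass is validated against an independent tap-summation reference
implementation (`atrous_convolve()` and friends), which is also the oracle
for the dilation identity: a rate-$r$ convolution equals a standard
convolution with the kernel zero-inflated to $k + (k-1)(r-1)$.

## Evaluation metrics

From the pixel confusion counts, `seg_score()` computes

$$\mathrm{ACC} = \frac{TP+TN}{TP+TN+FP+FN}, \quad
  \mathrm{JAC} = \frac{TP}{TP+FP+FN}, \quad
  \mathrm{DICE} = \frac{2\,TP}{2\,TP+FP+FN},$$

so $\mathrm{DICE} = 2\,\mathrm{JAC}/(1+\mathrm{JAC})$ identically — a
property asserted to $10^{-12}$ in the tests. Two conventions are
documented choices rather than consequences of the formulas:

* **Aggregation** is per-image: scores are computed per test image and then
  averaged (the ISIC challenge convention). Pixel-pooled aggregation would
  weight large lesions more heavily; `aggregate_scores()` exposes the
  per-image vectors so either view can be derived.
* **Empty union**: when $TP = FP = FN = 0$ (both masks empty), JAC and DICE
  are defined as 1 — agreement on the absence of a lesion is perfect
  agreement. The phantom generator never produces empty masks, but real
  dermoscopy panels can.

## The phantom generator

Real ISIC images cannot ship with a package, so the generator produces
dermoscopy-like phantoms with exact ground truth. A lesion is a star-convex
blob: an ellipse with random area fraction (default 5–30 % of the image),
aspect ratio (0.55–0.95) and orientation, whose contour radius is modulated
as $R(\varphi) \propto 1 + \delta(\varphi)$ by a random Fourier series of
orders 2–6 scaled by `border_irregularity` (default 0.25). The field is
renormalized so that the continuous blob area is independent of the
perturbation, which keeps the realized area fraction inside the configured
range; if a draw would not fit the frame, the perturbation is damped before
normalization, never the area. The mask is the exact pixel-center support
of the blob — there is no anti-aliasing between rendering and mask, an
invariant the tests assert.

Appearance and artifacts emulate the classic dermoscopy nuisances: the
lesion is darker and warmer than the skin tone, with a darker core; thin
dark Bezier hair curves occlude the image *without* altering the mask (as
in real ground truth); bright gel-bubble discs, a random linear
illumination gradient (5–15 %), occasional global contrast compression
(factor 0.55–0.8 with probability 0.4), and iid Gaussian texture noise
(sd 0.02). What the phantoms do **not** model: camera vignetting and color
calibration, ruler markings and ink, multi-focal or hypopigmented lesions,
and true dermoscopic texture (pigment networks, globules). A network that
segments phantoms well has demonstrably learned color/shape-based
figure–ground separation under these nuisances; that is evidence the
pipeline trains correctly end to end, not a claim about clinical
performance.

Preprocessing and augmentation follow the source pipeline:
nearest-neighbor resizing (`resize_nearest()`, the 0-based
`floor(i * H / H')` index map, which keeps masks strictly binary), and
random affine augmentation (`augment()`): rotation drawn from
$[15^\circ, 20^\circ]$ and scale/translation factors from $[-6, 5]$. The
published interval is ambiguous about units; here translation is read as
pixel offsets and scaling as a percentage deviation ($1 + u/100$), both
configurable. Images are resampled bilinearly with mirror-reflected
borders (zero fill would create dark corners resembling lesions); masks by
nearest neighbor with background fill. Augmentation is applied on the fly;
`write_samples()` can materialize an augmented dataset if a fixed enlarged
set is preferred.

## Problem sizes used by the test suite

The published experiments train on thousands of $192\times256$ ISIC images
on a GPU; the package's own checks are desk-scale by design and use the
paper's own preprocessing step (nearest-neighbor downsizing) to set the
working resolution:

* The **learning smoke test** renders 366 phantoms at $48\times64$,
  resizes them to $24\times32$, and trains the full 16-layer architecture
  with the published recipe (batch 16, $\alpha=0.01$, $\gamma_m=0.9$,
  $\lambda=0.005$, inverse-frequency class weights) for up to 30 epochs on
  256 of them, holding out 110. It asserts a mean held-out Jaccard index
  of at least 0.85 and a final training loss below 25 % of the initial
  loss. The network is fully convolutional, so the same weights and code
  paths run at any resolution.
* **Structural checks** (shape report, parameter count, translation
  covariance, receptive-field oracle) run at the full $192\times256$; the
  oracle-equivalence checks run on small random feature maps where the
  brute-force reference is exact.

Determinism is part of the contract: a master seed derives per-sample
seeds for the phantom set, the initializer seed fixes the weights, and
checkpoints embed every parameter including running statistics, so a
save/load round trip reproduces an evaluation report bit for bit.

## Numerical choices and degenerate inputs

* Batch-norm uses the population variance ($1/N$) of the mini-batch, with
  $\epsilon = 5\times10^{-5}$ guarding zero-variance (e.g. constant)
  batches; running statistics are the 0.9-momentum exponential average.
* The loss clamps probabilities at $10^{-12}$; the training loop aborts
  with a diagnostic when the loss or the predictions become non-finite
  (divergence), rather than silently continuing.
* Argmax ties go to background; an all-zero final layer therefore predicts
  an empty mask.
* `resize_nearest()` with the target equal to the source is the identity;
  nearest-neighbor resampling can only permute/duplicate values, so binary
  masks stay binary through every resize and mask augmentation.
* Convolution kernels must have odd spatial extent so that "same" padding
  is symmetric; the effective padding is $(k_\text{eff}-1)/2$ per side.
* Training memory is dominated by the im2col patch matrices; they are
  cached for backprop reuse only below 64 MB per layer and rebuilt on the
  fly above that, so high-resolution runs trade some time for a bounded
  footprint.

## Known limitations

* No GPU path and no autodiff: the backward pass covers exactly the layer
  types of this architecture.
* The inverse-frequency class weights make the argmax decision
  recall-biased: at the training optimum the network over-calls ambiguous
  pixels as lesion (the implied threshold on the unweighted posterior is
  well below 0.5), so residual errors concentrate in a roughly one-pixel
  over-segmentation ring around the boundary. At very small working
  resolutions that ring is a substantial fraction of a lesion's area and
  depresses the mean Jaccard index even when the classification is
  otherwise correct; the effect shrinks as resolution or lesion size
  grows.
* Phantom realism is deliberately limited (see above); reported phantom
  scores do not transfer to ISIC benchmarks.
* The ISIC folder loader reads PNG only; JPEG images must be converted
  beforehand.
* Per-image aggregated ACC/JAC/DICE is the only reporting convention
  implemented; thresholded challenge variants of the Jaccard index are out
  of scope.
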