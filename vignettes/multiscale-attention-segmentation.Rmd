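---
title: "Multi-magnification attention segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-magnification attention segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bile ducts are thin epithelial rings that mark portal areas in
Masson-stained liver sections.  Segmenting them from whole-slide images is
hard for two reasons that shape everything in this package:

* **Context vs. detail.**  A pathologist zooms out to recognize a portal
  area and zooms in to delineate the duct wall.  A single-magnification
  patch loses one or the other.  The network here therefore consumes a
  *pair* of co-centered patches — one at high magnification (the
  prediction target) and one at half that magnification (twice the field
  of view) — through two encoders with separate weights.
* **Extreme class imbalance.**  Duct wall pixels are a fraction of a
  percent of the slide.  Training uses the focal loss, which multiplies
  cross-entropy by $(1-p_t)^\gamma$ so that the millions of easy
  background pixels contribute almost nothing.

## The model

Both 256×256 patches pass through a reduced residual encoder (stem plus
three downsampling stages at channel widths $w, 2w, 4w, 4w$; width
multiplier $w$ defaults to 8).  The bottleneck sits at output stride 16
(configurable to 8).  Each bottleneck is enriched by dense atrous spatial
pyramid pooling: five 3×3 branches at dilation rates (3, 6, 12, 18, 24),
each seeing the concatenation of the input and all previous branch
outputs, followed by a 1×1 projection back to the input width.  Rates that
reach the feature-map size are clamped with a warning; at a 16×16
bottleneck the two largest rates clamp to 15.

**Alignment.**  The low-magnification patch covers twice the field of view
of the high patch, so its feature map is misaligned with the prediction
target everywhere except the center.  `central_crop_align()` crops the
central half of the low-branch feature map in each dimension (rows and
columns $[S/4, 3S/4)$ for size $S$) and bilinearly resizes back to
$S \times S$; after this, position $(i, j)$ in both maps covers the same
tissue.  Cropping happens on *features*, not pixels, so the low branch
still sees its full context before alignment.

**Attention fusion.**  With $H$ the high-branch features and $L$ the
aligned low-branch features,

$$Y = (1 + \sigma(L)) \odot H.$$

The sigmoid gate lies in $(0, 1)$, so $H \le Y \le 2H$ elementwise for
nonnegative (post-ReLU) $H$: low-magnification context can at most double
an activation, never veto it.  The limits are exact — $\sigma(0)$ gives
$1.5H$, saturation gives $H$ and $2H$ — and the identity
$Y - H = \sigma(L) \odot H$ is tested to machine precision.  The ablation
alternative concatenates the two maps and merges with a 1×1 convolution.

**Decoder.**  The fused bottleneck is bilinearly upsampled to the
factor-4 grid (twice ×2 from stride 16, once from stride 8), concatenated
with a 1×1 projection of the high branch's factor-4 features, merged by
two 3×3 convolutions, classified by a 1×1 convolution, and bilinearly
upsampled to the input resolution.  Only the high branch feeds the skip:
it is the prediction target, and the low branch's factor-4 features are
spatially misaligned at that stage.  Without the decoder, the classifier
applies directly to the fused bottleneck and a single bilinear upsample
restores full resolution.

## Numerical core

No deep-learning runtime is used.  The package carries its own compact
toolkit: convolution as im2col (compiled) plus BLAS matrix products,
bilinear resampling as separable interpolation matrices (so its adjoint is
a transpose), explicit hand-derived backward passes for every stage, and
Adam.  Correctness is pinned by the test suite rather than by convention:
forward convolution against a direct-loop oracle, every backward against
central finite differences, and the assembled network against a
directional-derivative check that exercises all stages jointly.

Numerical choices worth knowing:

* Bilinear resampling uses half-pixel centers with clamped borders; rows
  of the interpolation matrix sum to 1, so constants survive resampling
  exactly.  Pyramid levels use ceiling division for odd sizes.
* Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before logs.
* The predicted mask is the class argmax; an exact $p = 0.5$ tie breaks to
  background, making degenerate (all-zero-weight) models predict empty
  masks deterministically.
* Windows are 0-based, half-open $[o, o + 256)$; patch centers are stored
  in base-level (level-0) pixel coordinates.
* Low-magnification windows that extend past the image are
  reflection-padded — black borders would be far outside the stain color
  distribution.
* He initialization; biases start at zero; the seed in `model_config()`
  drives all weight draws.  Batch normalization is omitted: at the
  package's default scale (width 8, batches of 8) training is stable
  without it, and removing it keeps the evaluation path identical to the
  training path.

## Losses and metrics

The two-class focal loss uses the symmetric extension $p_t = p$ for
foreground pixels and $p_t = 1 - p$ for background, so background
contributes loss as well — restricting the loss to positive pixels would
let the model drift to all-foreground.  $\gamma = 0$ recovers
cross-entropy exactly (an identity, not an approximation, and tested as
such).  The focusing exponent defaults to $\gamma = 1$, the best-scoring
setting in the gamma ablation; the classical focal-loss default of 2 is
one flag away.  At $p_t = 0.9$, $\gamma = 2$ the per-pixel loss is exactly
1/100 of cross-entropy.

Scores are precision, recall, F1 and IoU from pooled pixel counts
(micro-averaging), matching their pixel-level definitions; macro-averaging
per patch would overweight nearly-empty patches.  True negatives enter no
score.  When a denominator is zero the score reports 0 with a `degenerate`
flag; an alternative "empty agreement = 1" policy is available because
neither convention is canonical.  The identity $\mathrm{IoU} =
F_1 / (2 - F_1)$ holds exactly for pooled counts and is property-tested.

## The synthetic scene generator

Real annotated Masson-stained slides are not redistributable, so the
package generates its own study conditions: 512×512 scenes with

* **ducts** — thin-walled annuli (lumen 6–14 px, wall 3–6 px) in a
  red-purple epithelial hue (the foreground class; the mask marks exactly
  the wall pixels);
* **arteries** — thicker-walled annuli (wall 9–14 px) in a nearby hue, the
  classic false-positive source: a model that keys only on color cannot
  separate them from ducts;
* **fibrosis** — a smooth low-frequency blue-green texture field whose
  high quantile defines the fibrosis annotation used by the retention
  filter;
* additive Gaussian pixel noise (σ = 0.02) over a pink-lavender
  hepatocyte-like background.

Three ducts and two arteries per scene put foreground prevalence near
0.4% of pixels — the imbalance regime that motivates the focal loss.
Structures are placed by rejection sampling, fully inside the image and
non-overlapping; a spec too crowded to place fails loudly.  Identical
specs (including seed) are bit-reproducible, and per-scene seeds derive
from the master seed by a fixed hash
(`(master * 2654435761 + index * 97) mod 2^31 - 1`), so manifests do not
depend on generation order.  Train/test splits are by scene, never by
patch, mirroring case-level splits: no tile of a test scene can leak into
training.

What the generator does **not** emulate: stain variability, scanner
artifacts, tissue folds, veins as a separate class, or the enormous
texture diversity of real hepatocyte background.  Passing the end-to-end
test shows the architecture can exploit co-centered context and survive
class imbalance — it says nothing about clinical performance on real
slides.

## Patch extraction defaults

The sliding window is 256 px.  The stride defaults to the window
(non-overlapping) for dataset building and to half the window for
stitched inference, where overlap smooths seams; overlapping tile
probabilities are averaged (bounded and order-independent, unlike max- or
logit-pooling).  The retention filter keeps a pair if its high-patch
footprint contains at least one annotated structure pixel
(`min_pixels = 1`): presence, not area, is the stated criterion, and the
threshold is configurable.

## Problem sizes

The test suite and the acceptance script run on desk-scale sizes chosen
once: gradient checks on 32-px models with width 2; training behaviour on
64-px models with width 4; the end-to-end run on 20 scenes of 512×512
(about 40 retained training pairs), 300 Adam steps at batch 8 and
learning rate $10^{-3}$, which reaches a pooled test IoU above 0.5; and a
five-axis ablation sweep (fusion, crop, pyramid pooling, decoder, and
$\gamma \in \{0,\dots,4\}$) at a deliberately short training budget that
verifies every variant trains, evaluates and reports coherent metrics —
the sweep checks completeness, not ranking.

## Known limitations

* One fusion point (at the bottleneck), two branches, two classes; no
  multi-scale repetition of the attention gate.
* The full-scale pretrained ResNet-101 backbone is not bundled; the
  reduced backbone trains from random initialization.
* Whole-image stitching is a convention of this package (averaged
  probabilities, argmax ties to background), not a claim about how
  patch-level predictions are best aggregated clinically.
* The CNN toolkit is single-threaded per sample and sized for hundreds of
  optimization steps, not for slide-scale training.
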