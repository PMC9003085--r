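# macnseg

Semantic segmentation of bile ducts in Masson-stained liver histology from
**pairs of co-centered patches at two magnifications**, for researchers who
want a fully inspectable, desk-scale implementation of multi-magnification
attention fusion — patch geometry, network, loss, metrics and ablations —
with no deep-learning runtime dependency.

## The method

A pathologist identifies a portal area at low magnification and traces the
duct wall at high magnification.  The pipeline mirrors that:

1. **Pyramid + patch pairs.**  A bilinear image pyramid halves the slide
   level by level.  A 256×256 window tiles the high-magnification level;
   for each tile, the low-magnification patch is the 256×256 window of the
   next level centered at the same tissue location, so the high patch's
   field of view is exactly the central half of the low patch's.  A
   retention filter keeps only pairs whose footprint contains annotated
   structures (duct, artery, vein, fibrosis), rebalancing away from plain
   hepatocyte tiles.
2. **Dual-encoder network with attention fusion.**  Two separately
   parameterized residual encoders process the two patches.  Bottleneck
   features pass through dense atrous spatial pyramid pooling; the
   low-magnification features are aligned by a central crop + bilinear
   resize; fusion is a sigmoid-gated attention

   **Y = (1 + σ(L)) ⊙ H**

   so low-magnification context can at most double a high-magnification
   activation (H ≤ Y ≤ 2H for post-ReLU H).  A skip-connection decoder
   restores full resolution.
3. **Focal loss** FL(p_t) = −(1 − p_t)^γ log p_t handles the ~0.4%
   foreground prevalence (γ defaults to 1; γ = 0 is exactly cross-entropy).
4. **Metrics** are precision, recall, F1 and IoU from pooled (micro-averaged)
   pixel counts, with the exact identity IoU = F1 / (2 − F1).

Everything runs on a hand-verified numeric core (im2col convolutions +
BLAS, interpolation-matrix resampling, explicit adjoint backward passes,
Adam); the test suite checks every gradient against finite differences.
A seedable generator of histology-like scenes (duct annuli, thicker-walled
artery distractors in a nearby hue, fibrosis texture, Gaussian noise)
provides exact ground truth so the whole pipeline is testable end to end.

## Worked example

```r
library(macnseg)

# a seeded synthetic cohort: 4 scenes, split at scene level
ds <- generate_dataset(4, scene_spec(image_size = c(256L, 256L),
                                     n_ducts = 2L, n_arteries = 1L),
                       seed = 42, train_fraction = 0.5)

# co-centered 128 px patch pairs at a 2x magnification ratio,
# filtered to structure-bearing footprints
pd <- build_patch_dataset(ds, window = 128L)
length(pd$train)                     # 8 training pairs
#> [1] 8

# train a small dual-branch attention model with focal loss
cfg <- train_config(model = model_config(input_size = 128L,
                                         backbone_width_multiplier = 4L,
                                         seed = 1L),
                    batch_size = 4L, max_steps = 400L, seed = 1L)
fit <- macn_train(cfg, pd$train)
round(fit$losses[c(1, 200, 400)], 4) # focal loss collapses on easy pixels
#> [1] 0.2018 0.0087 0.0028

ev <- macn_evaluate(fit$model, pd$test)
ev$metrics                           # micro-averaged over all test patches
#> precision 0.593  recall 0.519  F1 0.553  IoU 0.383

# the analytic identity behind the loss choice: an easy pixel (p_t = 0.9)
# is down-weighted 100-fold at gamma = 2
p <- matrix(0.9, 1, 1); y <- matrix(1, 1, 1)
cross_entropy(p, y) / focal_loss(p, y, gamma = 2)
#> [1] 100
```

The tiny cohort above runs in ~2 minutes; the full study conditions
(20 scenes of 512×512, 300 steps at batch 8, ~10 minutes on one CPU)
reach test IoU above 0.6 and are exercised by the acceptance script and
the test suite.

A thin command-line interface over the same functions lives at
`inst/cli/macnseg.R` (subcommands `generate-data`, `extract-patches`,
`train`, `evaluate`, `ablate`, `predict`, each taking a YAML config plus
`--seed`/`--out`/`--log-level`).

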