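---
title: "Two-stage adversarial meniscus segmentation with object-aware maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage adversarial meniscus segmentation with object-aware maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(menseg)
```

## The problem

The menisci are two thin, crescent-shaped fibrocartilage pads between the
femoral and tibial cartilage of the knee. Segmenting them automatically in
coronal MR volumes is hard for three compounding reasons: the structure is
thin and small, so in a whole 512×512 slice the meniscus occupies well under
2% of the pixels (severe class imbalance); the collateral and cruciate
ligaments sit immediately next to the menisci at nearly the same signal
intensity, so intensity-driven segmenters leak into them (over-segmentation);
and the intensity within the meniscus itself is inhomogeneous, so parts of it
are missed (under-segmentation).

`menseg` implements a two-stage pipeline that addresses each failure mode:

1. **Localization.** A six-class 2D U-Net labels whole coronal slices as
   background, femur, femoral cartilage, tibia, tibial cartilage, or
   meniscus. Multi-class training gives the thin classes anatomical context
   and mitigates the imbalance a meniscus-versus-rest segmenter suffers. The
   two largest 3-d connected components of the predicted meniscus class
   become the medial and lateral candidates, and a margin-padded box around
   each is resampled to 64×64.
2. **Refinement.** Inside each region of interest (ROI), a two-class U-Net
   generator `G` is trained adversarially against an encoder-style
   discriminator `D`. The generator minimizes
   `λ·L_GAN(G, D) + L_SEG(G)` with `λ = 0.04`, where `L_SEG` is mean binary
   cross-entropy against the ground truth and `L_GAN` is the conventional
   conditional-GAN objective. The discriminator is conditioned on an
   **object-aware map**: instead of concatenating the image with the mask as
   a second channel, the image is multiplied element-wise by the probability
   map (fake pairs) or the binary ground truth (real pairs). Zeroed
   background cannot influence `D`, so the adversarial signal concentrates on
   the meniscus region and penalizes leakage into ligament-like structures.

The four-way ablation mirrors this construction: method A is a two-class
U-Net on whole images; method B segments inside localized ROIs without
adversarial training; method C adds a conventional concatenation-conditioned
cGAN; method D is the full object-aware variant.

## The std-margin ROI rule

The ROI margin is derived from the variability of the meniscus extent across
slices. For each in-plane axis we pool, over all foreground-bearing slices,
the per-slice minimum and maximum coordinate of the component, and take the
standard deviation of that pooled sample, rounded to the nearest integer, as
the margin on that axis. The ROI is the global bounding box extended by the
margin and clamped to the volume. A component whose extent varies strongly
from slice to slice therefore receives a wider safety margin. Two
interpretations of "standard deviation" are exposed (`margin_mode`):
population (divide by *n*, the default) and sample (*n* − 1).

The slice axis has no "per-slice extrema" of its own, so the rule is extended
by exchanging the roles of slice and column: per-column minimum and maximum
slice indices are pooled and their rounded standard deviation is the z
margin. We use one volumetric box per meniscus (per-slice crops from a fixed
in-plane window) rather than a box per slice, which keeps the stage-two
input geometrically consistent across a stack.

Two further choices close gaps the margin rule leaves open: in-plane ROI
sides are expanded symmetrically to at least `min_size` (default 32 px)
before resampling to 64×64, so upsampling never exceeds 2×; and the
medial/lateral assignment uses each component's x-centroid relative to the
image midline together with the knee's laterality flag (the medial meniscus
lies toward the body midline, i.e. at higher column indices in a right knee).
Degenerate localizations — a single component, or both major components on
one side — produce a one-sided result with a warning rather than an error,
because they occur routinely with imperfect localizers.

## Losses and their numerical treatment

The discriminator loss is the negated classical objective
`-(log D(real) + log(1 − D(fake)))`; the per-pixel segmentation loss is
standard mean binary cross-entropy. (Printed forms of this objective
sometimes carry a sign slip in the second cross-entropy term; the
implementation follows the standard definition.) The generator's adversarial
term defaults to the non-saturating form `−log D(fake)`, because the direct
minimax form `log(1 − D(fake))` has vanishing gradients exactly when the
generator needs them most; the minimax form remains available via
`gan_form = "minimax"`.

Probabilities are clipped to `[ε, 1 − ε]` with `ε = 1e-7` before every
logarithm. Two further numerical choices matter in practice:

* **Adversarial gradient clipping.** When the discriminator wins decisively,
  `−1/D(fake)` explodes and the adversarial gradient can exceed the
  segmentation gradient by orders of magnitude, destabilizing the generator.
  Per batch, the weighted adversarial gradient is rescaled so its norm never
  exceeds `adv_grad_clip` (default 1) times the segmentation gradient norm.
  When the two terms are balanced the clip is inactive and `λ` alone sets
  the mixture.
* **Score clamping.** Discriminator scores are clamped to the open interval
  `(1e-12, 1 − 1e-12)` so that saturated logits cannot round to exactly 0
  or 1 in floating point.

* **Failed-fit restarts.** A small fraction of weight initializations parks
  a thin-structure segmenter in the all-background basin, where the loss
  decreases while the foreground Dice stays near zero. If the best
  validation DSC after training falls below a wide failure threshold
  (`min_val_dsc`, 50% for stage two, 10% for the localizer — an order of
  magnitude below typical fits), training restarts once or twice from a
  deterministically derived seed (+1000 per attempt). The guard applies
  identically at every `λ`, so the `λ = 0` ablation identity is preserved,
  and runs remain exactly reproducible.

Training alternates one discriminator step and one generator step per batch,
with Adam on both networks. With `λ = 0` the discriminator is never built and
the loop *is* supervised training: weight initialization, the discriminator,
and batch shuffling draw from three separate RNG streams derived from the
seed, so the `λ = 0` generator trajectory is bit-identical to the supervised
one. This identity is the basis of the method-B/method-D ablation contract
and is asserted in the tests.

Other conventions: convolution blocks are 3×3 convolution → batch
normalization → ReLU with same-padding; down-sampling is 2×2 max-pooling and
up-sampling a 2×2 transposed convolution; skip connections concatenate
channels; the head is a 1×1 convolution with softmax, so outputs match the
input resolution exactly. Inputs not divisible by `2^depth` are
reflect-padded and cropped back. Weights are He-initialized. Per-pixel argmax
breaks ties toward the lowest class code. Evaluation metrics with a zero
denominator are reported as undefined (`NA`) and excluded from cohort
aggregation — never coerced to 0 or 100; cohort summaries use the sample
(n − 1) standard deviation across patients.

## The phantom generator

Clinical knee MR volumes cannot ship with a package, so `menseg` includes a
synthetic phantom generator whose cases reproduce the *structure* of the
segmentation problem: a femoral condyle mass and a tibial plateau with 2–4 px
cartilage rims facing a joint space; two thin wedge-shaped menisci (peak
thickness 4–6 px at 128², under 2% of pixels on meniscus-bearing slices) near
the left and right joint-space margins; vertical collateral-ligament strips
flanking each meniscus and a central cruciate-like band, all within
`distractor_contrast` (default 5% of the dynamic range) of the meniscus
intensity and labeled background; a smooth multiplicative bias field and a
within-meniscus intensity modulation (inhomogeneity); additive Gaussian
noise; and per-case affine plus low-frequency elastic jitter so shape and
size vary between patients. Geometry is 2-d extruded with smooth z-modulation
of the meniscus extent, so per-slice extrema vary and the std-margin rule is
actually exercised. Every volume is z-score normalized. Each case is a pure
function of `(parameters, case seed)`.

An intensity-window baseline (`threshold_segment()`) reliably leaks into the
distractor strips (PPV far below 90% on default phantoms), reproducing the
over-segmentation failure mode the object-aware discriminator targets.

What the phantoms deliberately do **not** model: MR physics (no Rician noise
by default, though a config switch could add it at the normalized intensities
the difference is minor), realistic texture, pathology such as tears, partial
volume effects, or anatomically faithful meniscus horn shapes. Passing the
phantom ablation therefore demonstrates that the pipeline's machinery —
localization, ROI extraction, adversarial refinement, evaluation — behaves as
designed under the intended data regime; it does not certify clinical
performance.

## Desk-scale study conditions

The shipped experiment configuration is sized for a single CPU:

* 40 phantom patients at 128×128×16, split 70/15/15 into train/validation/
  test by largest-remainder rounding (ties resolved toward the later split).
* Networks with depth 4 and base width 8. Widths double per level but are
  capped at 16 channels (`max_width = 2 × base_width`): at these image sizes
  halving the spatial grid while doubling channels keeps the cost of *every*
  level constant, so uncapped doubling spends most of its time in the deep
  layers for marginal benefit on piecewise-smooth phantoms.
* Stage-1 training uses class-weighted cross-entropy (inverse-frequency
  weights normalized to unit mean pixel weight). With unweighted loss the
  meniscus class — 0.25% of pixels — contributes so little that a localizer
  at this training budget never predicts it; balanced weighting is the
  standard remedy and is exposed as `class_weights`.
* Training budgets: localizer 10 epochs × 64 slices; whole-image baseline 6
  epochs × 64 slices; stage two 8 epochs × 192 ROI slices, batch 16, Adam
  with learning rate 3e-3 throughout. The stage-1 localizer is trained once
  per seed and shared across methods B/C/D for a controlled comparison;
  training and validation ROIs come from ground-truth labels (stable
  targets), test-time ROIs from predicted labels.

On held-out phantoms this configuration reaches mean meniscus DSC in the
high 80s to mid 90s for the ROI-based methods, with the whole-image baseline
far behind — the ordering, not the absolute values, is the reproducible
quantity at this scale. `scripts/acceptance.R` re-runs the full ablation from scratch and the
test suite asserts the orderings across three seeds.

## Known limitations

* The CNN engine is CPU-bound dense arithmetic; it is sized for desk-scale
  experiments, not for 512×512 clinical volumes at training time (inference
  at 512² works but is slow).
* The ablation trends are stochastic at this scale. With six test patients
  per seed, a single mislocalized meniscus moves a cohort mean by several
  percentage points; the acceptance checks therefore average across seeds
  and sides.
* Batch-norm running statistics make eval-mode outputs depend on the exact
  training trajectory; reproducibility is guaranteed only for identical
  seeds in the same numerical environment.
* The medial/lateral rule assumes roughly centered knees; strongly off-center
  acquisitions would need a configurable midline.
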