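---
title: "Supervised SOM classification of macrofungi images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised SOM classification of macrofungi images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

`mycosom` classifies macrofungi species (the motivating collection covers
seven *Mycena* and *Marasmius* species) from RGB photographs. Instead of a
conventional dense softmax classifier, the framework extracts deep
convolutional features and classifies them with a Kohonen self-organizing
map (SOM) adapted for supervised use:

1. A compact four-block CNN (3×3 convolutions with 32/64/128/256 filters,
   each block ending in batch normalization, ReLU, and 2×2 max pooling)
   turns a 224×224×3 image into a 14×14×256 feature map — 50,176 values
   when flattened.
2. A rectangular SOM grid (reference setting 20×20 neurons, initial radius
   σ₀ = 1.0, initial learning rate α₀ = 0.5, 5000 iterations) is trained
   competitively on those feature vectors: at iteration *t* one training
   vector *x* is drawn at random, its best matching unit (BMU) — the
   neuron with minimal Euclidean distance ‖x − w‖ — is found, and every
   neuron moves toward *x* by
   w ← w + α(t)·h(t)·(x − w), where
   h(t) = exp(−d²/(2σ(t)²)) is a Gaussian kernel over grid coordinates
   and σ(t) = σ₀·exp(−t/τ) the shrinking neighborhood radius.
3. After training, each neuron is labeled with the majority class of the
   training vectors mapped to it; a new image is classified by the label
   of its BMU.

Two alternative heads are provided for comparison on the same features: a
sine-activation Kolmogorov–Arnold layer
y = W₂·sin(W₁x + b₁) + b₂ (W₁ ∈ ℝ^128×256, W₂ ∈ ℝ^7×128) on the CNN's
global-average-pooled 256-vector, and a two-backbone ensemble head that
concatenates 768- and 2048-dimensional backbone features into a unified
2816-vector classified by linear(2816→512) → ReLU → dropout 0.5 →
linear(512→7).

Model quality is summarized by macro-averaged metrics (precision, recall,
specificity, F1), the Gorodkin multiclass Matthews correlation
coefficient, one-vs-rest AUC, and two accuracies (see below). Two models'
confusion matrices can be compared with a chi-square procedure.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `separability` | 1.0 | synthetic class-signal strength in [0, 1] |
| `rows × cols` | 20 × 20 | SOM grid (10 × 10 for pooled backbone features) |
| `sigma0` | 1.0 | initial neighborhood radius (grid-cell units) |
| `alpha0` | 0.5 | initial SOM learning rate |
| `n_iter` | 5000 | SOM training iterations (one vector per iteration) |
| `tau` | `n_iter` | decay time constant of σ(t) and α(t) |
| `learning_rate` | 1e-3 | Adam step size for CNN/KAN/ensemble training |
| `lr_step`, `lr_gamma` | 7, 0.1 | step schedule: lr × 0.1 every 7 epochs |
| `batch_size` | 32 | minibatch size |
| `dropout` | 0.5 | dropout after the 512-unit layers |
| `train_frac` | 0.7 | stratified train share; per class `floor(0.7·n)` |

Hyperparameter search, where wanted, samples the published grids (batch
size {16, 32, 64}, learning rate {1e-2, 1e-3, 1e-4}, weight decay {1e-3,
1e-4, 1e-5}) uniformly at random (`random_search()`), optionally without
replacement so that 27 trials enumerate the full grid.

## Design choices where the design was open

* **Learning-rate decay of the SOM.** Only the radius decay
  σ(t) = σ₀·exp(−t/τ) is prescribed; we use the same exponential form for
  α(t) by default (internal consistency), with an inverse-time
  alternative (`decay = "inverse_time"`, the default of the popular
  MiniSom implementation) selectable. τ defaults to `n_iter`.
* **Sampling.** One random training vector per iteration, drawn with
  replacement: the reference setting of 5000 iterations over ~1100
  training vectors implies non-epoch sampling.
* **Initialization.** SOM weights i.i.d. uniform on [0, 1]; CNN and
  ensemble weights He-normal; KAN weights uniform scaled by 1/√fan_in.
  All seeded; every fit is bit-reproducible.
* **Ties.** BMU ties and majority-vote ties resolve to the smallest index
  in row-major order; max-pooling ties route the gradient to the first
  window position. Neurons that receive no training vectors inherit the
  label of the nearest labeled neuron in weight space.
* **Two accuracies.** The published macro-accuracy formula
  (1/K)·Σ TPᵢ/(TPᵢ+FPᵢ+FNᵢ) is the macro-averaged Jaccard index, not the
  conventional accuracy; `macro_metrics()` reports it as `accuracy` and
  reports `accuracy_standard = trace/total` alongside. Headline
  comparisons in this package use `accuracy_standard`.
* **MCC.** The multiclass MCC is computed in the standard Gorodkin form
  and is validated in the tests against the identity with the
  correlation of one-hot indicator matrices (covariances summed over
  class columns).
* **AUC for SOM predictions.** A SOM has no native class probabilities;
  `class_scores()` scores class *k* by minus the distance to the nearest
  neuron labeled *k*. The arg-max of these scores coincides with the BMU
  prediction, making them valid ranking scores for one-vs-rest AUC. Ties
  in the AUC indicator count ½ by default (Mann–Whitney convention); a
  strict mode is available.
* **Chi-square layout.** The comparison procedure builds, by default, a
  K×2K table: rows are actual classes, columns are model A's then model
  B's prediction counts. Note a caveat: this layout conflates each
  model's own class–prediction association with the *difference* between
  models — two identical, accurate models still yield a significant
  statistic (the table is [A|A], whose statistic is twice the
  independence statistic of A). The `correct_counts` layout (2×K: models
  × per-class correct predictions) is a cleaner two-sample homogeneity
  test — identical models give statistic 0, p = 1 — and is available via
  `layout = "correct_counts"`. Expected counts of zero are avoided by
  pruning all-zero rows/columns; the statistic is undefined otherwise.
* **KAN head input width.** The hidden layer's weight shape (128×256)
  requires a 256-dimensional input, matching the CNN's pooled vector;
  the head is trained on frozen extracted features by default.
* **Ensemble backbones.** Pretrained vision transformers/residual
  networks are out of scope; backbones are injected as feature-extractor
  callables. `backbone_stub()` is an explicitly synthetic stand-in (block
  averaging + fixed random projection) that emits the published widths
  (768, 2048) so the concatenation contract and the classification block
  are fully testable.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` reproduces the *composition* of the motivating
collection: 7 classes with 222, 228, 229, 243, 220, 227, 213 images
(1582 total), split 70/30 per class with the floor rule. Each class gets
an analyzable visual signature — a base hue at 2πk/K on the hue circle, an
oriented sinusoidal texture at 2+k cycles per image with random phase, and
an elliptical "cap" blob whose eccentricity grows with the class index —
mixed with class-independent illumination jitter and Gaussian noise scaled
by 1 − separability. At `separability = 0` all classes are identically
distributed; at 1 they are distinguishable by construction (a
nearest-centroid classifier on mean RGB already exceeds 0.9 accuracy,
which the tests verify as an oracle before relying on the fixture).

Passing tests on these images therefore demonstrates that the *machinery*
learns a known-learnable structure end to end; they do not demonstrate
performance on real fungal photographs, whose intra-class variation
(pose, background, lighting, growth stage) is far richer than hue + texture
+ one blob. The published headline numbers on the real collection are not
reproducible here and are not targeted.

## Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end CNN-SOM
experiment at a reduced scale chosen as this package's reference
demonstration: 7 classes × 50 images at 32×32 pixels (so block-4 features
are 2×2×256 = 1024-dimensional), at most 10 training epochs without
augmentation (the augmentation policy is the long-training regime; a
10-epoch run is too short to benefit), and the published SOM setting
(20×20, σ₀ = 1.0, α₀ = 0.5, 5000 iterations). Architecture-determined
dimensions (50,176; 2816; 7) are verified at full 224-pixel input size.

Other numerical details: convolutions use stride 1 and zero-padding 1 (the
only choice mapping 224 → 14 over four 2×2 poolings); images are scaled to
[0, 1] without mean/std standardization; batch-norm uses population
variance with momentum 0.1 running statistics for inference; early
stopping monitors the loss of a stratified 10% hold-out of the training
split with patience 5; softmax cross-entropy is computed with the
log-sum-exp trick; quantization error is recorded at initialization and
every 10% of SOM iterations. Feature standardization before the SOM is off
by default (optional `standardize` flag in `som_fit()`).

## Known limitations

* The CNN trainer is a plain-R implementation; it is practical at the
  tested sizes but not at ImageNet scale, and there is no GPU path.
* `backbone_stub()` carries no pretrained knowledge; ensemble and
  backbone-SOM variants exercise plumbing and training dynamics, not
  transfer learning.
* The default chi-square layout inherits the conflation caveat described
  above; for a pure "are these two models different?" question use
  `layout = "correct_counts"` (or a dedicated paired test such as
  McNemar's, which is out of scope here).
* PNG export quantizes pixels to 8 bits; bit-exact determinism statements
  apply to in-memory float images.
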