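---
title: "Methods: distribution-augmented contrastive one-class screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distribution-augmented contrastive one-class screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Cytology-based cervical cancer screening asks a reader to find rare
abnormal squamous cells — high-grade squamous intraepithelial lesions
(HSIL) and "atypical squamous cells, cannot exclude HSIL" (ASC-H) — among
hundreds of thousands of normal (NILM, *negative for intraepithelial
lesion or malignancy*) cells. Labeled abnormal examples are scarce;
normal tiles are abundant. `cytoscreen` therefore treats screening as
**one-class classification (OCC)**: it learns what normal looks like and
flags everything that does not fit.

The pipeline has three stages:

1. **Pretraining** — a convolutional encoder is trained on normal-only
   tiles with the SimCLR contrastive objective (NT-Xent). For each anchor
   two stochastic views are produced (random resized crop, horizontal
   flip, color jitter, random grayscale, Gaussian blur); views of the same
   anchor are positives, everything else in the batch is a negative.
2. **One-class scoring** — the frozen encoder's pre-projection embedding
   `h` is scored against the normal class with a Gaussian kernel density
   estimate (KDE), a one-class SVM, or a Gaussian mixture. Anomaly score
   orientation is uniform: higher = more abnormal. Slide-level calls
   aggregate tile embeddings (element-wise mean or maximum) and score the
   slide representation with a KDE fit on normal training slides.
3. **Localization** — because the KDE log-density is differentiable in
   `h`, a GradCAM attention map can be driven directly by the anomaly
   score: channel weights are spatial means of the score's gradient on the
   last convolutional stage, and the rectified weighted feature-map sum,
   upsampled and min-max normalized, highlights the abnormality-driving
   region. Boxes are cut from the heatmap by relative thresholding
   (default 0.5 × max) and 8-connected components (minimum component
   area 16 px), and evaluated against ground truth with intersection over
   union (IOU), each ground-truth box scored by its best IOU (0 when
   nothing is predicted, so misses are penalized).

## Distribution augmentation

Plain one-class contrastive learning tends to collapse toward uniform
representations. **Distribution augmentation (DA)** counters this by
enlarging the training distribution with transformed copies, each copy
treated as a *different distribution*: the copies are additional anchors,
and anchors from different distributions are negatives of one another. No
distribution-prediction head is used.

Two schemes are provided:

* **Color DA** — each tile is copied three times with a hue rotation
  drawn uniformly from the intervals `[-16, 16]`, `[-16, -12]` and
  `[12, 16]` degrees (a threefold expansion). Because hue is now the
  signal separating distributions, the per-view color jitter *excludes*
  hue for this scheme.
* **Rotation DA** — exact right-angle rotations 0°, 90°, 180°, 270°
  (fourfold expansion; 0° is the identity distribution).

Hue is the natural augmentation axis in cytopathology because staining
varies systematically between labs and scanners (a *batch effect*): a
model exposed to wide hue variation should rely less on absolute color
and generalize better across sources.

Two readings of the color copy count are possible ("threefold" vs "three
additional"); the package uses total-count semantics — three color
distributions, four rotation distributions — and the interval list is
configurable if a user wants an explicit identity interval. Hue shifts
are sampled per instance (once per copy), not per epoch.

## Model and training recipe

* Encoders: `resnet18` (512-d embeddings, the fidelity target) and
  `tiny_cnn`, a four-block conv/batch-norm/ReLU encoder with global
  average pooling (64-d), for CPU-scale work. Both are built on the
  package's own layer library (im2col convolutions in compiled code,
  manual backpropagation) since no deep-learning framework is assumed.
* Projection head: 8 hidden Linear–BatchNorm–ReLU layers (hidden width
  512, output 128 by default; both widths are configurable, as neither
  is a pinned quantity of the method). The deep head follows
  contrastive-OCC practice. Batch normalization is essential here: in
  pilot runs an unnormalized deep head collapsed to the uniform fixed
  point of NT-Xent (loss pinned at `log(2N-1)`).
* Optimization: SGD (momentum 0.9) with a single cosine-annealing cycle
  from learning rate 0.01, batch size 32 anchors (64 views), temperature
  0.2, up to 100 epochs; the checkpoint of the **last** epoch is used
  downstream (no early stopping).
* Downstream embeddings are the pre-projection features `h`, extracted in
  inference mode with no DA and no view transforms.

## One-class scorers and evaluation

* **KDE**: isotropic Gaussian kernels on raw embeddings, bandwidth 1.0 by
  default (Scott's rule available). Log-density via log-sum-exp; the
  anomaly score is the negative log-density.
* **OC-SVM** (`e1071`): radial kernel, `nu = 0.1`, kernel width
  `1/(d * var)`; score = negative decision value.
* **GMM**: one component by default — the closed-form multivariate-normal
  MLE — or EM via `mclust` for more components; a `1e-6` ridge is always
  added to covariance diagonals. Score = negative log-likelihood.
* Thresholding for precision/recall/F1 is the nearest-rank `q = 0.95`
  quantile of the *normal-training* anomaly scores (abnormal iff score
  strictly above); threshold-free AUC (rank statistic, ties counted 1/2)
  is always reported alongside. Abnormal is the positive class
  everywhere.
* Evaluation uses 4-fold cross-validation (75/25), grouped by slide by
  default so no slide straddles folds; one-class models are fit on the
  normal rows of the training folds only. A semi-supervised K-means
  classifier (K = 4, cluster-majority labels, ties broken to abnormal —
  the screening-safe direction) and a supervised MLP baseline (`nnet`)
  complete the comparison set. t-SNE (exact, package-internal since no
  t-SNE package is available in the target environment) provides the
  customary embedding plots.

## The synthetic data generator

Real cytology cohorts are not redistributable, so the package ships a
seeded generator whose tiles carry the statistical cues the pipeline
assumes:

* cells are cytoplasm ellipses (pale pink or cyan, HSV-defined) with one
  nucleus ellipse; cell count per tile is shifted Poisson (mean 3, at
  least one); later cells overpaint earlier ones;
* normal cells have nucleus-to-cytoplasm (N:C) area ratios in
  `[0.05, 0.15]`; abnormal cells in `[0.4, 0.8]`, with the nucleus value
  channel darkened (× 0.6), saturation raised, and a radial sinusoidal
  boundary perturbation (amplitude 0.3 of the radius, 3–7 lobes) — the
  enlarged, hyperchromatic, irregular nuclei pathologists look for;
* every abnormal cell gets the tight box of its cytoplasm ellipse
  (0-based, half-open); normal tiles have no boxes;
* a global hue rotation applied after drawing emulates a staining batch
  effect between datasets;
* everything is driven by per-tile derived seeds: identical spec + seed
  reproduce files byte for byte.

What it does **not** emulate: overlapping cell sheets, mucus/debris
artifacts, atrophy (a benign change whose parabasal-cell sheets mimic
HSIL), focus variation, and scanner noise. Passing tests on
synthetic tiles therefore demonstrate that the pipeline's machinery is
correct and that its inductive biases pick up N:C-ratio/chromasia cues;
they are not evidence of clinical performance.

## Desk-scale study conditions

CPU-scale experiments (tests and `scripts/acceptance.R`) use: 600 normal
32 × 32 synthetic training tiles, the `tiny_cnn` encoder, projection head
8 × 128 → 64, 20 training epochs, batch 32, lr 0.01, temperature 0.2 —
i.e. the full training recipe with the encoder, head width and epoch
count scaled to minutes of CPU. The color-DA comparison trains the color model
for 7 epochs over its threefold-expanded instance set, matching the
gradient-step count of the 20-epoch generic run (a compute-matched
comparison). Held-out evaluation uses 100 + 100 fresh tiles; slide-level
experiments use 40 normal + 50 abnormal evaluation slides of 20 tiles
(abnormal slides 30% abnormal tiles) with 20 extra normal slides for the
slide-KDE fit; localization uses 50 abnormal 64-px tiles against a
random-box baseline with matched box count and sizes.

One caveat discovered in pilot runs and worth stating: with the standard
view-transform defaults, the *generic* model's color jitter already spans
±28.8° of hue, which covers a +20° test-set hue shift; at that shift
magnitude the generic model is therefore nearly hue-invariant by
construction and the color-DA advantage the method shows under large
cross-dataset staining shifts may not be resolvable. The package keeps
the faithful defaults rather than handicapping the baseline.

## Numerical choices and degenerate inputs

* NT-Xent normalizes projections internally; zero rows are rejected. The
  loss is non-negative for any batch (the positive term is one of the
  denominator's terms) and invariant to global orthogonal rotation of the
  projections; its analytic gradient is finite-difference checked.
* KDE in high dimension underflows naive kernel sums; all densities use
  log-sum-exp. A KDE whose score gradient vanishes at a tile yields an
  all-zero GradCAM map, returned flagged (`degenerate = TRUE`) rather
  than renormalized.
* Background pixels are grayscale luminance ≥ 230/255 — white
  liquid-based-cytology backgrounds make luminance thresholding the
  natural definition of "background". Exclusion is strict
  (> 50%), so a tile at exactly half background is retained.
* The 5% abnormal-area rule uses annotation-box area, the only geometry
  available from nucleus-centred 90 × 90 boxes; a tile with an
  abnormal-class box centre inside is abnormal regardless of area.
* Cross-validation folds are grouped by slide by default, preventing
  leakage of slide-level staining signatures across folds; ungrouped
  tile-level folds are available.
* K-means empty clusters are retried with fresh seeds (cap 5) before
  rejection; kmeans/MLP/GMM seeds derive deterministically from the
  user seed.
* 8-bit round trips: hue rotation is exact in float and within ±1 level
  after one quantization, ±2 after two.

## Known limitations

* The ResNet18 path is structurally complete and gradient-checked but is
  not exercised at full 256-px/100-epoch scale in the test suite — that
  regime needs GPU-class hardware.
* The KDE stores its training set; scoring is O(m·n). Fine for the
  tile counts here, wasteful beyond ~10^5 training embeddings.
* Artifact exclusion is left to the user: `filter_tiles(artifact_hook=)`
  accepts any tile predicate, and no artifact detector is shipped (in
  practice this screening step is often done by human review).
* Heatmap-to-box extraction (relative threshold + connected components)
  is deliberately simple; no non-maximum suppression is applied.
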