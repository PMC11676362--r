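# cytoscreen

One-class screening of cervical cytology tiles with
distribution-augmented contrastive pretraining, density-based anomaly
scoring, and KDE-driven GradCAM localization.

## The problem

Cytology-based cervical cancer screening means finding rare high-grade
abnormal squamous cells (HSIL, ASC-H) among overwhelmingly normal (NILM)
cells. Labeled abnormal data is scarce and expensive; normal tiles are
abundant. `cytoscreen` is for computational pathology researchers who
want a **one-class** pipeline: learn the normal class only, flag
everything that falls outside it, and show *where* in the tile the
abnormality signal comes from.

## Method

1. **Contrastive pretraining on normal-only tiles.** An encoder
   f(·) (ResNet18, or a small CNN for CPU work) with a deep MLP
   projection head g(·) is trained with the NT-Xent loss: for a batch of
   N anchors with two stochastic views each (random resized crop, flip,
   color jitter, grayscale, blur), with z = g(f(view)),

       L_i = -log [ exp(cos(z_i, z_j)/τ) / Σ_{k≠i} exp(cos(z_i, z_k)/τ) ]

   with τ = 0.2, SGD lr 0.01, batch 32, cosine annealing.
   **Distribution augmentation (DA)** expands the one-class training set
   with transformed copies treated as distinct distributions — hue
   intervals [-16,16], [-16,-12], [12,16] degrees (color DA, 3x) or
   rotations 0/90/180/270 (rotation DA, 4x) — countering the uniformity
   collapse of one-class contrastive learning and, for color, targeting
   staining batch effects.

2. **One-class scoring on frozen embeddings h = f(tile).** The anomaly
   score is the negative Gaussian-KDE log-density of h under the normal
   training embeddings (OC-SVM and GMM scorers are included for
   comparison; K-means cluster-majority and a supervised MLP serve as
   semi-/fully-supervised references). Slide-level calls aggregate tile
   embeddings by element-wise mean or max and score the slide vector with
   a KDE over normal training slides. Evaluation: precision/recall/F1
   (abnormal positive, threshold = 0.95-quantile of normal-train scores)
   and rank-statistic AUC, under 4-fold cross-validation.

3. **Localization.** The KDE score is differentiable in h, so GradCAM
   can target the anomaly score itself: channel weights are spatial means
   of ∂score/∂A for the last conv stage's feature maps A; the rectified
   weighted sum, upsampled and normalized, is thresholded (0.5 × max) into
   8-connected components whose tight boxes are compared to ground truth
   by IOU.

A seeded synthetic cytology generator (cells as cytoplasm/nucleus
ellipses; abnormal cells with high nucleus-to-cytoplasm ratio, darkened
irregular nuclei; global hue shift as a staining batch effect; exact
ground-truth boxes) makes the whole pipeline testable end to end with no
external data. See `vignettes/cytoscreen-methods.Rmd` for the full
methods account.

## Worked example

```r
library(cytoscreen)

# 200 normal synthetic tiles; pretrain a small encoder for 5 epochs
spec  <- synthetic_spec(tile_size = 32, seed = 1)
train <- generate_tiles(spec, 200, 0)
ck <- pretrain(train$tiles, da_scheme("none"), view_config(),
               encoder_config("tiny_cnn", 32),
               projection_head_config(8, 128, 64),
               train_config(max_epochs = 5, seed = 1))

# KDE anomaly scores for held-out tiles (100 normal + 100 abnormal mix)
test <- generate_tiles(synthetic_spec(tile_size = 32, seed = 2), 50, 50)
emb_train <- embed_tiles(ck, train$tiles)
kde <- fit_kde(emb_train, bandwidth = 1)
sc  <- anomaly_score(kde, embed_tiles(ck, test$tiles))
auc_score(sc, test$labels)
#> [1] 0.9088

thr <- choose_threshold(anomaly_score(kde, emb_train), 0.95)
evaluate_predictions(ifelse(sc > thr, "abnormal", "normal"), test$labels)
#> precision    recall        f1
#>     0.944     0.680     0.791

# localize the abnormal cell in one 64-px tile
ab <- generate_tile(synthetic_spec(seed = 3), "abnormal")
kde64 <- fit_kde(embed_tiles(ck, generate_tiles(synthetic_spec(seed = 3),
                                                50, 0)$tiles), 1)
hm <- gradcam_kde(ck, kde64, ab$tile)
boxes_from_heatmap(hm, 0.5, 16)
#>   x0 y0 x1 y1 peak
#> 1 44 20 64 42    1
localization_report(list(t = boxes_from_heatmap(hm, 0.5, 16)),
                    list(t = ab$boxes))$summary["mean"]
#>      mean
#> 0.8349901
```

Even this 90-second toy run separates held-out abnormal tiles
(AUC ≈ 0.91) and the KDE-driven GradCAM box overlaps the annotated
abnormal cell (IOU ≈ 0.83). The 0.95-quantile threshold trades recall for
precision, as a screening triage should.

A thin CLI over the same functions is installed at
`inst/cli/cytoscreen.R` (`synth-tiles`, `pretrain`, `embed`, `score`,
`slide-score`, `localize`, `folds`, `balance`).

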