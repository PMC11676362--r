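# Downstream evaluation: semi-supervised K-means classifier, supervised MLP
# baseline, metrics, cross-validation and slide-level scoring.

#' K-means cluster-majority classifier
#'
#' Fits K-means on all training embeddings (normal and abnormal), labels
#' each cluster by the majority training label (ties break to abnormal --
#' the screening-safe direction), and predicts by nearest centroid.
#'
#' @param x `n x d` training embeddings.
#' @param labels `"normal"`/`"abnormal"` training labels (both present).
#' @param K number of clusters (default 4).
#' @param seed integer seed.
#' @param nstart random restarts per attempt.
#' @param retry_cap re-seeding attempts when a cluster comes back empty.
#' @return An object of class `kmeans_classifier`.
#' @export
fit_kmeans_classifier <- function(x, labels, K = 4L, seed = 1L,
                                  nstart = 10L, retry_cap = 5L) {
  x <- as.matrix(x)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  km <- NULL
  for (attempt in seq_len(retry_cap)) {
    km <- try(with_seed(derive_seed(seed, attempt),
                        stats::kmeans(x, centers = K, nstart = nstart,
                                      iter.max = 100)),
              silent = TRUE)
    if (!inherits(km, "try-error") && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("K-means failed to produce ", K, " non-empty clusters")
  cluster_label <- vapply(seq_len(K), function(k) {
    tab <- table(factor(labels[km$cluster == k],
                        levels = c("normal", "abnormal")))
    if (tab["abnormal"] >= tab["normal"]) "abnormal" else "normal"
  }, character(1))
  structure(list(centers = km$centers, cluster_label = cluster_label, K = K),
            class = "kmeans_classifier")
}

#' @export
predict.kmeans_classifier <- function(object, newdata, ...) {
  d2 <- cross_sqdist(as.matrix(newdata), object$centers)
  object$cluster_label[max.col(-d2, ties.method = "first")]
}

#' Supervised MLP baseline on frozen embeddings
#'
#' Single-hidden-layer neural network (`nnet`) trained on labeled
#' embeddings; its class probability is used for AUC. Serves as the
#' fully supervised reference against the one-class models.
#'
#' @param x `n x d` embeddings.
#' @param labels binary labels (`normal`/`abnormal`).
#' @param seed integer seed (weights initialization).
#' @param size hidden units.
#' @param decay weight decay.
#' @param maxit optimizer iterations.
#' @return Object of class `mlp_classifier`.
#' @export
fit_supervised_mlp <- function(x, labels, seed = 1L, size = 32L,
                               decay = 1e-4, maxit = 200L) {
  x <- as.matrix(x)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  y <- as.numeric(labels == "abnormal")
  fit <- with_seed(seed,
    nnet::nnet(x, y, size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE, MaxNWts = 1e6))
  structure(list(fit = fit), class = "mlp_classifier")
}

#' @export
predict.mlp_classifier <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- as.numeric(stats::predict(object$fit, as.matrix(newdata)))
  if (type == "prob") p else ifelse(p > 0.5, "abnormal", "normal")
}

#' Rank-based AUC of anomaly scores
#'
#' Probability that a random abnormal outscores a random normal, with ties
#' counted 1/2 (equivalent to the Mann-Whitney statistic).
#'
#' @param scores anomaly scores (higher = more abnormal).
#' @param labels binary labels, `"abnormal"` positive (or logical/0-1).
#' @return AUC in [0, 1]; `NA` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    labels == "abnormal"
  } else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision / recall / F1 for binary screening predictions
#'
#' Abnormal is the positive class throughout.
#'
#' @param predictions predicted labels.
#' @param labels true labels.
#' @return Named numeric vector `precision, recall, f1` (NA when
#'   undefined).
#' @export
evaluate_predictions <- function(predictions, labels) {
  tp <- sum(predictions == "abnormal" & labels == "abnormal")
  fp <- sum(predictions == "abnormal" & labels == "normal")
  fn <- sum(predictions == "normal" & labels == "abnormal")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Cross-validated downstream evaluation
#'
#' For each fold: the one-class scorers (`kde`, `ocsvm`, `gmm`) are fitted
#' on the NORMAL rows of the training folds only, a threshold is set at the
#' `q`-quantile of the normal-train scores, and precision/recall/F1/AUC are
#' measured on the full validation fold. The semi-supervised K-means
#' classifier and the supervised MLP use all training rows.
#'
#' @param embeddings `n x d` matrix aligned with `manifest` rows.
#' @param manifest data frame with `label` and `fold` columns (see
#'   [make_folds()]).
#' @param model one of `"kde"`, `"ocsvm"`, `"gmm"`, `"kmeans"`, `"mlp"`.
#' @param q threshold quantile for the one-class scorers.
#' @param seed integer seed (K-means / MLP / GMM initialization).
#' @param ... extra arguments passed to the fitting function
#'   (e.g. `bandwidth`, `nu`, `n_components`, `K`).
#' @return A `metrics_report`: per-fold data frame plus mean and sd of each
#'   metric.
#' @export
cross_validate <- function(embeddings, manifest, model = "kde", q = 0.95,
                           seed = 1L, ...) {
  stopifnot(nrow(embeddings) == nrow(manifest),
            !is.null(manifest$fold), !is.null(manifest$label))
  folds <- sort(unique(manifest$fold))
  rows <- lapply(folds, function(f) {
    tr <- manifest$fold != f
    va <- !tr
    if (length(unique(manifest$label[va])) < 2) {
      stop("validation fold ", f, " lacks a class")
    }
    xtr <- embeddings[tr, , drop = FALSE]
    ytr <- manifest$label[tr]
    xva <- embeddings[va, , drop = FALSE]
    yva <- manifest$label[va]
    if (model %in% c("kde", "ocsvm", "gmm")) {
      xfit <- xtr[ytr == "normal", , drop = FALSE]
      stopifnot(all(ytr[ytr == "normal"] == "normal"))
      scorer <- switch(model,
        kde = fit_kde(xfit, ...),
        ocsvm = fit_ocsvm(xfit, ...),
        gmm = fit_gmm(xfit, seed = derive_seed(seed, f), ...))
      thr <- choose_threshold(anomaly_score(scorer, xfit), q)
      sc <- anomaly_score(scorer, xva)
      pred <- ifelse(sc > thr, "abnormal", "normal")
      auc <- auc_score(sc, yva)
    } else if (model == "kmeans") {
      fit <- fit_kmeans_classifier(xtr, ytr, seed = derive_seed(seed, f), ...)
      pred <- predict(fit, xva)
      auc <- NA_real_
    } else if (model == "mlp") {
      fit <- fit_supervised_mlp(xtr, ytr, seed = derive_seed(seed, f), ...)
      p <- predict(fit, xva, type = "prob")
      pred <- ifelse(p > 0.5, "abnormal", "normal")
      auc <- auc_score(p, yva)
    } else stop("unknown model: ", model)
    c(fold = f, evaluate_predictions(pred, yva), auc = auc)
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  metrics <- c("precision", "recall", "f1", "auc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), numeric(1)))
  structure(list(model = model, per_fold = per_fold, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Cross-validated %s (%d folds), abnormal = positive class\n",
              x$model, nrow(x$per_fold)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Slide-level anomaly scoring
#'
#' Aggregates tile embeddings per slide (element-wise mean or maximum),
#' fits a KDE on the representations of the normal training slides, and
#' reports per-slide anomaly scores and the AUC over the evaluation slides.
#'
#' @param tile_embeddings `n x d` matrix of tile embeddings.
#' @param slide_ids slide id per tile row.
#' @param slide_labels named vector (or data frame `slide_id, label`)
#'   mapping slide ids to `normal`/`abnormal`.
#' @param train_slides slide ids (all normal) used to fit the KDE; the
#'   remaining slides are scored.
#' @param method `"mean"` or `"max"` aggregation.
#' @param bandwidth KDE bandwidth on slide representations.
#' @return List with `scores` (named), `auc`, `method`.
#' @export
slide_level_score <- function(tile_embeddings, slide_ids, slide_labels,
                              train_slides, method = c("mean", "max"),
                              bandwidth = 1.0) {
  method <- match.arg(method)
  if (is.data.frame(slide_labels)) {
    slide_labels <- stats::setNames(slide_labels$label, slide_labels$slide_id)
  }
  reps <- aggregate_slides(tile_embeddings, slide_ids, method)
  if (!length(train_slides)) stop("no normal training slides")
  if (any(slide_labels[train_slides] != "normal")) {
    stop("training slides must all be normal")
  }
  scorer <- fit_kde(reps[train_slides, , drop = FALSE], bandwidth)
  eval_ids <- setdiff(rownames(reps), train_slides)
  sc <- anomaly_score(scorer, reps[eval_ids, , drop = FALSE])
  names(sc) <- eval_ids
  list(scores = sc, auc = auc_score(sc, slide_labels[eval_ids]),
       method = method, representations = reps)
}

#' KDE score spectrum with representative tiles
#'
#' Histograms the anomaly scores per class and samples representative tiles
#' from chosen score bands (the "what does a tile at this score look like"
#' inspection). Optionally writes an image sheet.
#'
#' @param scores anomaly scores aligned with `tiles`.
#' @param labels class labels aligned with `scores` (optional).
#' @param tiles list of tiles (optional; needed for the sheet).
#' @param n_bins histogram bins.
#' @param bands list of `(lo, hi)` score bands to sample from; defaults to
#'   terciles of the observed range.
#' @param n_per_band tiles sampled per band.
#' @param seed sampling seed.
#' @param file optional PNG path for the sample sheet.
#' @return List with `histogram` (data frame: bin mids and per-class
#'   counts) and `band_samples` (list of index vectors; empty when a band
#'   contains no scores).
#' @export
kde_score_spectrum <- function(scores, labels = NULL, tiles = NULL,
                               n_bins = 30, bands = NULL, n_per_band = 3,
                               seed = 1L, file = NULL) {
  if (!is.null(tiles) && length(tiles) != length(scores)) {
    stop("tiles must align with scores")
  }
  rng <- range(scores)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  if (rng[1] == rng[2]) breaks <- rng[1] + seq(-0.5, 0.5, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  classes <- if (is.null(labels)) rep("all", length(scores)) else labels
  hist_df <- data.frame(mid = mids)
  for (cl in unique(classes)) {
    cnt <- graphics::hist(scores[classes == cl], breaks = breaks,
                          plot = FALSE)$counts
    hist_df[[cl]] <- cnt
  }
  if (is.null(bands)) {
    qs <- stats::quantile(scores, c(0, 1 / 3, 2 / 3, 1))
    bands <- list(c(qs[1], qs[2]), c(qs[2], qs[3]), c(qs[3], qs[4]))
  }
  band_samples <- with_seed(seed, lapply(bands, function(b) {
    idx <- which(scores >= b[1] & scores <= b[2])
    if (!length(idx)) return(integer(0))
    sort(sample(idx, min(n_per_band, length(idx))))
  }))
  if (!is.null(file) && !is.null(tiles)) {
    sel <- unlist(band_samples)
    if (length(sel)) {
      nc <- max(lengths(band_samples))
      grDevices::png(file, width = 120 * nc, height = 120 * length(bands))
      graphics::par(mfrow = c(length(bands), nc), mar = c(0.5, 0.5, 1.5, 0.5))
      for (b in seq_along(band_samples)) {
        for (i in band_samples[[b]]) {
          graphics::plot.new()
          graphics::rasterImage(grDevices::as.raster(
            tile_to_float(tiles[[i]])), 0, 0, 1, 1)
          graphics::title(sprintf("%.2f", scores[i]), cex.main = 0.9)
        }
        pad <- nc - length(band_samples[[b]])
        if (pad > 0) for (j in seq_len(pad)) graphics::plot.new()
      }
      grDevices::dev.off()
    }
  }
  list(histogram = hist_df, band_samples = band_samples, bands = bands)
}
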