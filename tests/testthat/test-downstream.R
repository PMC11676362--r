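# One-class scorers, metrics and cross-validated evaluation.

test_that("KDE log-density matches the closed form and a brute-force oracle", {
  # single training point at its mode, d = 2, h = 1: L = -ln(2*pi)
  x0 <- matrix(c(0.3, -1.2), 1)
  kde <- fit_kde(x0, 1)
  expect_equal(kde_log_density(kde, x0), -log(2 * pi), tolerance = 1e-12)
  # and the general closed form -(d/2) ln(2 pi h^2) at the mode
  for (h in c(0.5, 2)) {
    kde_h <- fit_kde(x0, h)
    expect_equal(kde_log_density(kde_h, x0), -log(2 * pi * h^2),
                 tolerance = 1e-12)
  }

  # brute-force kernel-sum oracle
  train <- cytoscreen:::with_seed(5, matrix(stats::rnorm(50 * 8), 50, 8))
  probes <- cytoscreen:::with_seed(6, matrix(stats::rnorm(10 * 8), 10, 8))
  kde2 <- fit_kde(train, 1.3)
  got <- kde_log_density(kde2, probes)
  h <- 1.3; d <- 8
  want <- apply(probes, 1, function(p) {
    k <- exp(-colSums((t(train) - p)^2) / (2 * h^2)) * (2 * pi * h^2)^(-d / 2)
    log(mean(k))
  })
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("KDE anomaly score grows with distance and flattens as bandwidth grows", {
  kde <- fit_kde(matrix(c(0, 0), 1), 1)
  sc <- anomaly_score(kde, rbind(c(0, 0), c(1, 0), c(3, 0), c(10, 0)))
  expect_true(all(diff(sc) > 0))              # monotone in distance for m = 1

  train <- cytoscreen:::with_seed(7, matrix(stats::rnorm(30 * 4), 30, 4))
  p <- cytoscreen:::with_seed(8, matrix(stats::rnorm(2 * 4), 2, 4))
  gap <- function(h) abs(diff(anomaly_score(fit_kde(train, h), p)))
  expect_lt(gap(100), gap(10))
  expect_lt(gap(1000), 1e-3)
})

test_that("KDE log-density gradient matches finite differences", {
  train <- cytoscreen:::with_seed(9, matrix(stats::rnorm(20 * 3), 20, 3))
  kde <- fit_kde(train, 0.8)
  x <- c(0.2, -0.4, 0.9)
  g <- cytoscreen:::kde_log_density_grad(kde, x)
  eps <- 1e-6
  for (j in 1:3) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    fd <- (kde_log_density(kde, xp) - kde_log_density(kde, xm)) / (2 * eps)
    expect_equal(g[1, j], fd, tolerance = 1e-6)
  }
})

test_that("GMM(1) equals the multivariate-normal MLE log-pdf", {
  x <- cytoscreen:::with_seed(11, matrix(stats::rnorm(200 * 3), 200, 3))
  gmm <- fit_gmm(x, 1)
  probes <- cytoscreen:::with_seed(12, matrix(stats::rnorm(5 * 3), 5, 3))
  mu <- colMeans(x)
  sig <- crossprod(sweep(x, 2, mu)) / nrow(x) + diag(1e-6, 3)
  want <- -mclust::dmvnorm(probes, mu, sig, log = TRUE)
  expect_equal(anomaly_score(gmm, probes), want, tolerance = 1e-6)

  # score is minimized near the sample mean
  far <- mu + 5
  expect_lt(anomaly_score(gmm, matrix(mu, 1)),
            anomaly_score(gmm, matrix(far, 1)))
})

test_that("GMM(1) recovers the generating mean within 3 standard errors", {
  n <- 1000
  x <- cytoscreen:::with_seed(13, cbind(stats::rnorm(n, 2, 1.5),
                                        stats::rnorm(n, -1, 1.5)))
  gmm <- fit_gmm(x, 1)
  se <- 1.5 / sqrt(n)
  expect_true(all(abs(gmm$means[, 1] - c(2, -1)) < 3 * se))
})

test_that("OC-SVM flags roughly a nu-fraction of its own training set", {
  x <- cytoscreen:::with_seed(14, matrix(stats::rnorm(300 * 4), 300, 4))
  oc <- fit_ocsvm(x, nu = 0.2)
  sc <- anomaly_score(oc, x)
  expect_true(all(is.finite(sc)))
  flagged <- mean(sc > 0)                    # beyond the learned boundary
  expect_lt(abs(flagged - 0.2), 0.1)
})

test_that("threshold selection follows the nearest-rank quantile rule", {
  expect_equal(choose_threshold(1:100, 0.95), 95)
  expect_equal(choose_threshold(1:100, 1.0), 100)   # flags nothing (strict >)
  same <- rep(4.2, 10)
  thr <- choose_threshold(same, 0.95)
  expect_equal(thr, 4.2)
  expect_equal(sum(same > thr), 0L)
  expect_error(choose_threshold(numeric(0)), "empty")
})

test_that("K-means cluster-majority classifier separates blobs and breaks ties to abnormal", {
  x <- rbind(cytoscreen:::with_seed(15, matrix(stats::rnorm(60, 0, 0.2), 30, 2)),
             cytoscreen:::with_seed(16, matrix(stats::rnorm(60, 5, 0.2), 30, 2)))
  y <- rep(c("normal", "abnormal"), each = 30)
  km <- fit_kmeans_classifier(x, y, K = 2, seed = 1)
  pred <- predict(km, x)
  expect_equal(unname(evaluate_predictions(pred, y)["f1"]), 1.0)

  # a tied cluster maps to abnormal: 2 of each label at one centre
  x2 <- rbind(matrix(0.01 * stats::rnorm(8), 4, 2),
              matrix(5 + 0.01 * stats::rnorm(8), 4, 2))
  y2 <- c("normal", "abnormal", "normal", "abnormal",
          rep("normal", 4))
  km2 <- fit_kmeans_classifier(x2, y2, K = 2, seed = 2)
  tied_label <- predict(km2, matrix(c(0, 0), 1))
  expect_equal(tied_label, "abnormal")
  expect_error(fit_kmeans_classifier(x, rep("normal", 60), K = 2), "both classes")
})

test_that("supervised MLP baseline fits separable data deterministically", {
  x <- rbind(cytoscreen:::with_seed(17, matrix(stats::rnorm(40, 0, 0.3), 20, 2)),
             cytoscreen:::with_seed(18, matrix(stats::rnorm(40, 4, 0.3), 20, 2)))
  y <- rep(c("normal", "abnormal"), each = 20)
  fit <- fit_supervised_mlp(x, y, seed = 3)
  p <- predict(fit, x, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit, x, type = "class"), y)
  fit2 <- fit_supervised_mlp(x, y, seed = 3)
  expect_identical(predict(fit2, x, type = "prob"), p)
})

test_that("AUC matches the pair-counting oracle and is monotone-invariant", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1),
                         c("abnormal", "abnormal", "normal", "normal")), 1.0)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9),
                         c("abnormal", "abnormal", "normal", "normal")), 0.0)
  expect_true(is.na(auc_score(1:3, rep("normal", 3))))

  pair_auc <- function(s, y) {
    pos <- s[y == "abnormal"]; neg <- s[y != "abnormal"]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  for (trial in 1:10) {
    s <- cytoscreen:::with_seed(trial, sample(seq(0, 1, by = 0.05), 30,
                                              replace = TRUE))
    y <- cytoscreen:::with_seed(trial + 100,
                                sample(c("normal", "abnormal"), 30, TRUE))
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), pair_auc(s, y), tolerance = 1e-12)
    expect_equal(auc_score(exp(3 * s), y), auc_score(s, y), tolerance = 1e-12)
  }
})

test_that("cross-validation fits one-class models on normal training rows only", {
  set.seed(19)
  n <- 120
  emb <- rbind(matrix(stats::rnorm(80 * 3), 80, 3),
               matrix(stats::rnorm(40 * 3, mean = 4), 40, 3))
  man <- data.frame(label = c(rep("normal", 80), rep("abnormal", 40)),
                    slide_id = rep(sprintf("s%02d", 1:12), each = 10))
  man <- make_folds(man, k = 4, group_by_slide = FALSE, seed = 2)
  rep_kde <- cross_validate(emb, man, "kde", bandwidth = 1)
  expect_equal(nrow(rep_kde$per_fold), 4L)
  expect_equal(rep_kde$summary$mean[rep_kde$summary$metric == "f1"],
               mean(rep_kde$per_fold$f1), tolerance = 1e-12)
  expect_gt(rep_kde$summary$mean[rep_kde$summary$metric == "auc"], 0.9)

  rep_km <- cross_validate(emb, man, "kmeans", K = 2)
  expect_equal(nrow(rep_km$per_fold), 4L)

  # a fold without both classes is rejected
  man_bad <- man
  man_bad$fold <- ifelse(man_bad$label == "abnormal", 1L,
                         rep_len(2:4, sum(man_bad$label == "normal")))
  expect_error(cross_validate(emb, man_bad, "kde"), "lacks a class")
})

test_that("slide-level scoring separates synthetic slide embeddings", {
  set.seed(20)
  # 6 normal train slides, 8 eval slides (4 normal, 4 abnormal), 5 tiles each
  mk <- function(sid, shift) {
    list(emb = matrix(stats::rnorm(5 * 4, mean = shift), 5, 4),
         ids = rep(sid, 5))
  }
  slides <- c(lapply(sprintf("tr%02d", 1:6), mk, shift = 0),
              lapply(sprintf("ev_n%02d", 1:4), mk, shift = 0),
              lapply(sprintf("ev_a%02d", 1:4), mk, shift = 3))
  emb <- do.call(rbind, lapply(slides, `[[`, "emb"))
  ids <- unlist(lapply(slides, `[[`, "ids"))
  labels <- stats::setNames(
    c(rep("normal", 10), rep("abnormal", 4)),
    c(sprintf("tr%02d", 1:6), sprintf("ev_n%02d", 1:4), sprintf("ev_a%02d", 1:4)))
  for (m in c("mean", "max")) {
    res <- slide_level_score(emb, ids, labels, sprintf("tr%02d", 1:6), m)
    expect_equal(res$auc, 1.0)
  }
  # all-identical tiles: mean and max representations coincide
  same <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_equal(aggregate_slide(same, "mean"), aggregate_slide(same, "max"))
})

test_that("score spectrum handles single-class and out-of-range bands", {
  sc <- cytoscreen:::with_seed(21, stats::rnorm(50))
  sp <- kde_score_spectrum(sc, labels = rep("normal", 50))
  expect_true("normal" %in% names(sp$histogram))
  expect_equal(sum(sp$histogram$normal), 50)

  sp2 <- kde_score_spectrum(sc, bands = list(c(100, 200)))
  expect_length(sp2$band_samples[[1]], 0L)

  sp3 <- kde_score_spectrum(sc, seed = 5)
  sp4 <- kde_score_spectrum(sc, seed = 5)
  expect_identical(sp3$band_samples, sp4$band_samples)
})

test_that("t-SNE projection is seeded, shaped, and robust to duplicates", {
  x <- cytoscreen:::with_seed(22, matrix(stats::rnorm(60 * 5), 60, 5))
  y1 <- tsne_project(x, perplexity = 8, seed = 4, max_iter = 120)
  expect_equal(dim(y1), c(60L, 2L))
  y2 <- tsne_project(x, perplexity = 8, seed = 4, max_iter = 120)
  expect_identical(y1, y2)

  dup <- x[rep(1:2, each = 30), ]
  y3 <- tsne_project(dup, perplexity = 8, seed = 1, max_iter = 60)
  expect_true(all(is.finite(y3)))
  expect_error(tsne_project(x[1:10, ], perplexity = 8), "perplexity")
})
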