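# IOU, connected components, heatmap -> box extraction, GradCAM.

test_that("iou matches the pixel-enumeration oracle", {
  a <- c(x0 = 0, y0 = 0, x1 = 2, y1 = 2)
  b <- c(x0 = 1, y0 = 1, x1 = 3, y1 = 3)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, c(x0 = 5, y0 = 5, x1 = 7, y1 = 7)), 0.0)
  expect_equal(iou(a, b), 1 / 7)

  pixel_iou <- function(p, q) {
    px <- expand.grid(x = p["x0"]:(p["x1"] - 1), y = p["y0"]:(p["y1"] - 1))
    qx <- expand.grid(x = q["x0"]:(q["x1"] - 1), y = q["y0"]:(q["y1"] - 1))
    keyp <- paste(px$x, px$y); keyq <- paste(qx$x, qx$y)
    length(intersect(keyp, keyq)) / length(union(keyp, keyq))
  }
  for (trial in 1:10) {
    cs <- cytoscreen:::with_seed(trial, sample(0:10, 8, replace = TRUE))
    p <- c(x0 = min(cs[1], cs[2]), y0 = min(cs[3], cs[4]),
           x1 = max(cs[1], cs[2]) + 1, y1 = max(cs[3], cs[4]) + 1)
    q <- c(x0 = min(cs[5], cs[6]), y0 = min(cs[7], cs[8]),
           x1 = max(cs[5], cs[6]) + 1, y1 = max(cs[7], cs[8]) + 1)
    expect_equal(iou(p, q), pixel_iou(p, q))
    expect_equal(iou(p, q), iou(q, p))
  }
})


test_that("connected components are 8-connected and match the propagation oracle", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
  lab <- connected_components(m)
  expect_equal(lab[1, 1], lab[2, 2])      # diagonal touch joins components
  expect_true(lab[4, 4] != lab[1, 1])
  expect_equal(max(lab), 2L)

  for (trial in 1:6) {
    mk <- cytoscreen:::with_seed(trial,
                                 matrix(stats::runif(12 * 12) < 0.4, 12, 12))
    got <- connected_components(mk)
    want <- propagate_components(mk)
    expect_equal(max(got), length(unique(want[want > 0])))
    # same partition: components agree up to label renaming
    for (k in seq_len(max(got))) {
      expect_equal(length(unique(want[got == k])), 1L)
    }
  }
})

test_that("boxes are extracted from heatmap components with area filtering", {
  hm <- matrix(0, 20, 20)
  hm[5:10, 3:8] <- 1                       # one 6x6 hot rectangle
  b <- boxes_from_heatmap(hm, min_area_px = 4)
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[1, 1:4]), c(x0 = 2, y0 = 4, x1 = 8, y1 = 10))

  expect_equal(nrow(boxes_from_heatmap(matrix(0, 8, 8))), 0L)

  hm2 <- matrix(0, 20, 20)
  hm2[2:7, 2:7] <- 0.9
  hm2[14:19, 14:19] <- 1.0
  b2 <- boxes_from_heatmap(hm2, rel_threshold = 0.5, min_area_px = 4)
  expect_equal(nrow(b2), 2L)
  expect_gte(b2$peak[1], b2$peak[2])       # sorted by peak, descending

  # components below min_area are dropped
  hm3 <- hm2
  hm3[10, 10] <- 1
  b3 <- boxes_from_heatmap(hm3, min_area_px = 4)
  expect_equal(nrow(b3), 2L)
})

test_that("localization report scores each ground truth by its best IOU", {
  gt <- list(t1 = data.frame(x0 = 0, y0 = 0, x1 = 4, y1 = 4),
             t2 = data.frame(x0 = c(1, 8), y0 = c(1, 8),
                             x1 = c(5, 12), y1 = c(5, 12)))
  rep1 <- localization_report(gt, gt)
  expect_true(all(rep1$per_box$best_iou == 1.0))
  expect_equal(unname(rep1$summary["mean"]), 1.0)

  none <- list(t1 = gt$t1[0, ], t2 = gt$t2[0, ])
  rep2 <- localization_report(none, gt)
  expect_true(all(rep2$per_box$best_iou == 0.0))

  expect_error(localization_report(list(a = gt$t1), gt), "ids")

  # assignment-free max matching agrees with exhaustive pairing
  pred <- list(t1 = data.frame(x0 = c(0, 2), y0 = c(0, 2),
                               x1 = c(3, 6), y1 = c(3, 6)),
               t2 = gt$t2)
  rep3 <- localization_report(pred, gt)
  exhaustive <- max(iou(gt$t1[1, ], pred$t1[1, ]), iou(gt$t1[1, ], pred$t1[2, ]))
  expect_equal(rep3$per_box$best_iou[rep3$per_box$tile == "t1"], exhaustive)
})

test_that("gradcam maps are normalized, tile-sized, and flag degenerate cases", {
  ck <- quick_checkpoint()
  spec <- synthetic_spec(tile_size = 16, seed = 55)
  norm <- generate_tiles(spec, 20, 0)
  emb <- embed_tiles(ck, norm$tiles)
  kde <- fit_kde(emb, 1.0)

  ab <- generate_tile(spec, "abnormal", seed = 99)
  hm <- gradcam_kde(ck, kde, ab$tile)
  expect_s3_class(hm, "heatmap")
  expect_equal(dim(hm$values), c(16L, 16L))
  expect_gte(min(hm$values), 0)
  expect_lte(max(hm$values), 1)

  # KDE with a single training point equal to the tile's own embedding:
  # the score gradient vanishes, so the map is degenerate
  own <- embed_tiles(ck, list(ab$tile))
  kde0 <- fit_kde(own, 1.0)
  hm0 <- gradcam_kde(ck, kde0, ab$tile)
  expect_true(hm0$degenerate)
  expect_true(all(hm0$values == 0))

  expect_error(gradcam_kde(ck, kde, ab$tile, target_layer = "nope"),
               "unknown layer")
})

test_that("gradcam channel weights match the per-channel loop oracle", {
  ck <- quick_checkpoint()
  spec <- synthetic_spec(tile_size = 16, seed = 56)
  kde <- fit_kde(embed_tiles(ck, generate_tiles(spec, 15, 0)$tiles), 1.0)
  tile <- generate_tile(spec, "abnormal", seed = 7)$tile
  hm <- gradcam_kde(ck, kde, tile)

  grads <- hm$gradients
  want <- numeric(dim(grads)[3])
  for (c in seq_len(dim(grads)[3])) {
    acc <- 0
    for (i in seq_len(dim(grads)[1])) for (j in seq_len(dim(grads)[2])) {
      acc <- acc + grads[i, j, c]
    }
    want[c] <- acc / (dim(grads)[1] * dim(grads)[2])
  }
  expect_equal(hm$channel_weights, want, tolerance = 1e-6)

  # independent route: for the default target (the GAP input) the analytic
  # weight is d score / d h_c divided by the spatial cell count
  dh <- -cytoscreen:::kde_log_density_grad(kde, embed_tiles(ck, list(tile)))
  hw <- prod(dim(grads)[1:2])
  expect_equal(hm$channel_weights, as.numeric(dh) / hw, tolerance = 1e-8)
})
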