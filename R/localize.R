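# Localization of abnormal cells: GradCAM driven by the differentiable KDE
# anomaly score, heatmap -> bounding-box extraction, and IOU evaluation.

#' GradCAM attention map from the KDE anomaly score
#'
#' The scalar target is the KDE anomaly score (negative log-density) of the
#' tile's embedding, so hot regions are the ones driving the abnormality
#' call. Channel weights are the spatial means of the target's gradient
#' with respect to the chosen feature maps; the map is the rectified
#' weighted sum of those maps, bilinearly upsampled to tile size and
#' min-max normalized. A map whose rectified response is identically zero
#' is returned as all zeros with `degenerate = TRUE`.
#'
#' @param checkpoint a [pretrain()] checkpoint or `cyto_model`.
#' @param kde_scorer a [fit_kde()] scorer over normal embeddings.
#' @param tile a [tile_record()] or H x W x 3 array.
#' @param target_layer encoder layer name (default: last convolutional
#'   stage, `"relu4"` for `tiny_cnn`, `"layer4"` for `resnet18`).
#' @return Object of class `heatmap`: `values` (H x W in [0, 1]),
#'   `degenerate`, `score`, `target_layer`, plus the raw feature maps,
#'   gradients and channel weights for inspection.
#' @export
gradcam_kde <- function(checkpoint, kde_scorer, tile, target_layer = NULL) {
  model <- if (inherits(checkpoint, "cyto_model")) checkpoint else checkpoint$model
  if (!inherits(kde_scorer, "kde_scorer")) stop("kde_scorer must be a fitted KDE")
  x <- tiles_to_batch(list(tile))
  ts <- dim(x)[1]
  target_layer <- target_layer %||% default_target_layer(model)
  tl <- nn_layer_index(model$encoder, target_layer)

  fw <- nn_forward(model$encoder, x, training = FALSE, collect = TRUE)
  h <- fw$out
  score <- anomaly_score(kde_scorer, h)
  dh <- -kde_log_density_grad(kde_scorer, h)     # d score / d h
  bk <- nn_backward(model$encoder, fw$caches, dh, stop_at = tl)
  grad <- bk$dx                                   # [Ho, Wo, 1, C]
  feat <- fw$outs[[tl]]
  dg <- dim(grad)
  weights <- colMeans(matrix(grad, dg[1] * dg[2], dg[4]))

  fm <- matrix(feat, dg[1] * dg[2], dg[4])
  cam <- matrix(pmax(fm %*% weights, 0), dg[1], dg[2])
  degenerate <- max(cam) <= 0
  up <- bilinear_resize(cam, ts, ts)
  up <- pmax(up, 0)
  if (!degenerate && max(up) > 0) up <- up / max(up)
  structure(list(values = up, degenerate = degenerate,
                 score = as.numeric(score), target_layer = target_layer,
                 feature_maps = array(feat, dg[c(1, 2, 4)]),
                 gradients = array(grad, dg[c(1, 2, 4)]),
                 channel_weights = weights),
            class = "heatmap")
}

#' 8-connected components of a binary mask
#'
#' Breadth-first labeling treating diagonal neighbors as connected.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (v - 1L) %% h + 1L
      cl <- (v - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          u <- (cc - 1L) * h + rr
          if (mask[u] && lab[u] == 0L) {
            lab[u] <- cur
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  lab
}

#' Extract predicted boxes from a heatmap
#'
#' Binarizes at `rel_threshold` x max, finds 8-connected components, drops
#' components smaller than `min_area_px` pixels, and returns the tight
#' bounding box of each remaining component (0-based, half-open), sorted by
#' peak activation descending.
#'
#' @param heatmap a [gradcam_kde()] result or a matrix in [0, 1].
#' @param rel_threshold relative threshold in (0, 1] (default 0.5).
#' @param min_area_px minimum component pixel count (default 16).
#' @return Data frame `x0, y0, x1, y1, peak` (possibly empty).
#' @export
boxes_from_heatmap <- function(heatmap, rel_threshold = 0.5,
                               min_area_px = 16) {
  v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  empty <- data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), peak = numeric(0))
  mx <- max(v)
  if (mx <= 0) return(empty)
  lab <- connected_components(v >= rel_threshold * mx)
  n <- max(lab)
  if (n == 0) return(empty)
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    data.frame(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
               x1 = max(idx[, 2]), y1 = max(idx[, 1]),
               peak = max(v[idx]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$peak), , drop = FALSE]
}

#' Intersection over union of two boxes
#'
#' Boxes are 0-based, half-open `[x0, x1) x [y0, y1)`; areas are pixel
#' counts.
#'
#' @param a,b numeric vectors (or one-row data frames) with `x0, y0, x1,
#'   y1`.
#' @return IOU in [0, 1].
#' @export
iou <- function(a, b) {
  a <- unlist(a[c("x0", "y0", "x1", "y1")])
  b <- unlist(b[c("x0", "y0", "x1", "y1")])
  iw <- max(min(a[3], b[3]) - max(a[1], b[1]), 0)
  ih <- max(min(a[4], b[4]) - max(a[2], b[2]), 0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  unname(inter / union)
}

#' Localization report: predicted vs ground-truth boxes
#'
#' Each ground-truth box is scored by its best (maximum) IOU over the
#' tile's predicted boxes -- 0 when there is no prediction, so missed
#' detections are penalized. Summaries are the per-tile mean and the
#' dataset box-plot statistics of the per-ground-truth IOUs.
#'
#' @param pred_boxes named list (by tile id) of predicted-box data frames.
#' @param gt_boxes named list (by tile id) of ground-truth-box data
#'   frames; ids must match `pred_boxes`.
#' @return List with `per_box` (tile, gt index, best IOU), `per_tile`
#'   (mean best IOU per tile) and `summary` (mean, median, quartiles).
#' @export
localization_report <- function(pred_boxes, gt_boxes) {
  if (!setequal(names(pred_boxes), names(gt_boxes))) {
    stop("tile ids of predictions and ground truth do not match")
  }
  per_box <- list()
  for (id in names(gt_boxes)) {
    gt <- gt_boxes[[id]]
    pr <- pred_boxes[[id]]
    if (is.null(gt) || !nrow(gt)) next
    for (g in seq_len(nrow(gt))) {
      best <- if (is.null(pr) || !nrow(pr)) 0 else
        max(vapply(seq_len(nrow(pr)),
                   function(p) iou(gt[g, ], pr[p, ]), numeric(1)))
      per_box[[length(per_box) + 1L]] <-
        data.frame(tile = id, gt_index = g, best_iou = best,
                   stringsAsFactors = FALSE)
    }
  }
  per_box <- if (length(per_box)) do.call(rbind, per_box) else
    data.frame(tile = character(0), gt_index = integer(0),
               best_iou = numeric(0))
  per_tile <- if (nrow(per_box)) {
    stats::aggregate(best_iou ~ tile, per_box, mean)
  } else data.frame(tile = character(0), best_iou = numeric(0))
  qs <- if (nrow(per_box)) stats::quantile(per_box$best_iou,
                                           c(0.25, 0.5, 0.75)) else
    rep(NA_real_, 3)
  list(per_box = per_box, per_tile = per_tile,
       summary = c(mean = if (nrow(per_box)) mean(per_box$best_iou) else NA_real_,
                   q25 = unname(qs[1]), median = unname(qs[2]),
                   q75 = unname(qs[3])))
}

#' Matched random-box baseline
#'
#' For each tile, places the same number of boxes with the same sizes as
#' the given predictions, uniformly at random inside the tile. Used as the
#' chance reference for localization quality.
#'
#' @param pred_boxes named list of predicted-box data frames.
#' @param tile_size tile side in pixels.
#' @param seed integer seed.
#' @return Named list of random-box data frames.
#' @export
random_box_baseline <- function(pred_boxes, tile_size, seed = 1L) {
  with_seed(seed, lapply(pred_boxes, function(pr) {
    if (is.null(pr) || !nrow(pr)) return(pr)
    out <- pr
    for (i in seq_len(nrow(pr))) {
      w <- pr$x1[i] - pr$x0[i]
      h <- pr$y1[i] - pr$y0[i]
      x0 <- sample.int(tile_size - w + 1L, 1L) - 1L
      y0 <- sample.int(tile_size - h + 1L, 1L) - 1L
      out[i, c("x0", "y0", "x1", "y1")] <- c(x0, y0, x0 + w, y0 + h)
    }
    out
  }))
}

#' Overlay ground-truth and predicted boxes on a tile
#'
#' Writes a PNG with ground truth in red and predictions in blue.
#'
#' @param tile tile pixels.
#' @param gt,pred box data frames.
#' @param file output PNG path.
#' @param heatmap optional heatmap blended under the boxes.
#' @export
write_overlay <- function(tile, gt, pred, file, heatmap = NULL) {
  x <- tile_to_float(tile)
  ts <- dim(x)[1]
  if (!is.null(heatmap)) {
    v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
    x[, , 1] <- clamp01(0.6 * x[, , 1] + 0.4 * v)
  }
  grDevices::png(file, width = ts * 4, height = ts * 4)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(c(0, ts), c(ts, 0), asp = 1)
  graphics::rasterImage(grDevices::as.raster(x), 0, ts, ts, 0)
  draw <- function(df, col) {
    if (is.null(df) || !nrow(df)) return()
    for (i in seq_len(nrow(df))) {
      graphics::rect(df$x0[i], df$y1[i], df$x1[i], df$y0[i],
                     border = col, lwd = 3)
    }
  }
  draw(gt, "red"); draw(pred, "blue")
  grDevices::dev.off()
  invisible(file)
}
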