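#' t-SNE projection of embeddings
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding: Gaussian
#' input affinities calibrated to the target perplexity by per-point binary
#' search, symmetrized, then a momentum gradient descent on the
#' Student-t low-dimensional affinities with early exaggeration. Intended
#' for the few-hundred-to-few-thousand tile embeddings this pipeline
#' visualizes.
#'
#' @param x `n x d` embedding matrix (`n > 3 * perplexity`).
#' @param perplexity effective neighbor count (default 30).
#' @param seed seed for the random initialization.
#' @param max_iter gradient iterations (default 500).
#' @param labels optional class labels; used for coloring when `file` is
#'   given.
#' @param file optional PNG path for a scatter plot.
#' @return `n x 2` coordinate matrix.
#' @export
tsne_project <- function(x, perplexity = 30, seed = 1L, max_iter = 500L,
                         labels = NULL, file = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity) stop("need n > 3 * perplexity points")

  d2 <- cross_sqdist(x, x)
  diag(d2) <- Inf
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, ]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0 } else {
        pr <- w / sw
        nz <- pr > 0
        h <- -sum(pr[nz] * log(pr[nz]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, ] <- w / max(sum(w), .Machine$double.eps)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  })
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200
  for (iter in seq_len(max_iter)) {
    exag <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    yd2 <- cross_sqdist(y, y)
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (exag * p - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    cols <- if (is.null(labels)) "grey30" else
      ifelse(labels == "abnormal", "firebrick", "steelblue")
    graphics::plot(y, col = cols, pch = 19, cex = 0.6,
                   xlab = "t-SNE 1", ylab = "t-SNE 2")
    if (!is.null(labels)) {
      graphics::legend("topright", legend = unique(labels),
                       col = ifelse(unique(labels) == "abnormal",
                                    "firebrick", "steelblue"), pch = 19)
    }
    grDevices::dev.off()
  }
  y
}
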