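# One-class scorers over normal-class embeddings. All scorers share the
# orientation "higher anomaly score = more abnormal".

#' Gaussian kernel-density one-class scorer
#'
#' Fits a Gaussian KDE to normal-class embeddings. The log-density at a
#' probe `x` is
#' `log( (1/m) sum_i (2 pi h^2)^(-d/2) exp(-||x - x_i||^2 / (2 h^2)) )`
#' and the anomaly score is its negative, so the score is differentiable
#' in `x` (the property GradCAM exploits).
#'
#' @param x `m x d` matrix of normal embeddings.
#' @param bandwidth kernel bandwidth `h` (> 0), or `"scott"` for
#'   `sigma * m^(-1/(d+4))` with `sigma` the mean per-dimension standard
#'   deviation. Default 1 on raw embeddings.
#' @return An object of class `kde_scorer`.
#' @export
fit_kde <- function(x, bandwidth = 1.0) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite embeddings")
  if (identical(bandwidth, "scott")) {
    sig <- mean(apply(x, 2, stats::sd))
    if (!is.finite(sig) || sig == 0) sig <- 1
    bandwidth <- sig * nrow(x)^(-1 / (ncol(x) + 4))
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  structure(list(kind = "kde", train = x, bandwidth = bandwidth,
                 d = ncol(x)), class = c("kde_scorer", "oneclass_scorer"))
}

# cross squared Euclidean distances, q: n x d probes vs t: m x d train
cross_sqdist <- function(q, t) {
  qn <- rowSums(q^2)
  tn <- rowSums(t^2)
  d2 <- outer(qn, tn, "+") - 2 * tcrossprod(q, t)
  pmax(d2, 0)
}

#' KDE log-density at probe points
#' @param scorer a [fit_kde()] scorer.
#' @param x probe matrix (`n x d`) or single vector.
#' @return Numeric vector of log-densities.
#' @export
kde_log_density <- function(scorer, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  h <- scorer$bandwidth
  d2 <- cross_sqdist(as.matrix(x), scorer$train)
  const <- -0.5 * scorer$d * log(2 * pi * h^2) - log(nrow(scorer$train))
  apply(-d2 / (2 * h^2), 1, log_sum_exp) + const
}

# gradient of the KDE log-density with respect to the probe(s)
kde_log_density_grad <- function(scorer, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  h <- scorer$bandwidth
  d2 <- cross_sqdist(x, scorer$train)
  lw <- -d2 / (2 * h^2)
  w <- exp(lw - apply(lw, 1, log_sum_exp))     # n x m softmax weights
  (w %*% scorer$train - x) / h^2
}

#' One-class support vector machine scorer
#'
#' Radial-kernel OC-SVM fitted on normal embeddings (via `e1071::svm`,
#' `type = "one-classification"`). The anomaly score is the negative
#' decision value, matching the orientation of the other scorers.
#'
#' @param x `m x d` matrix of normal embeddings.
#' @param nu the usual OC-SVM margin parameter (default 0.1); an upper
#'   bound on the training outlier fraction.
#' @param gamma kernel width; `"scale"` (default) uses
#'   `1 / (d * var(x))`.
#' @export
fit_ocsvm <- function(x, nu = 0.1, gamma = "scale") {
  x <- as.matrix(x)
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(x))
    gamma <- 1 / (ncol(x) * if (v > 0) v else 1)
  }
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  structure(list(kind = "ocsvm", fit = fit, nu = nu, gamma = gamma),
            class = c("ocsvm_scorer", "oneclass_scorer"))
}

#' Gaussian-mixture one-class scorer
#'
#' Fits a Gaussian mixture to normal embeddings and scores probes by their
#' negative log-likelihood. With one component (the default) the fit is the
#' closed-form multivariate-normal maximum-likelihood estimate; with more
#' components EM is run via `mclust` (full covariances). A small ridge is
#' always added to the covariance diagonals to guard against degeneracy.
#'
#' @param x `m x d` matrix of normal embeddings.
#' @param n_components number of mixture components (default 1).
#' @param ridge diagonal regularization added to each covariance.
#' @param seed seed for the EM initialization (unused when
#'   `n_components = 1`).
#' @export
fit_gmm <- function(x, n_components = 1L, ridge = 1e-6, seed = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (n_components == 1L) {
    mu <- colMeans(x)
    sig <- crossprod(sweep(x, 2, mu)) / nrow(x)   # MLE (1/m) covariance
    params <- list(weights = 1,
                   means = matrix(mu, ncol = 1),
                   sigmas = array(sig, c(d, d, 1)))
  } else {
    fit <- with_seed(seed,
      mclust::Mclust(x, G = n_components, modelNames = "VVV",
                     verbose = FALSE))
    if (is.null(fit)) stop("GMM EM failed to converge")
    params <- list(weights = fit$parameters$pro,
                   means = fit$parameters$mean,
                   sigmas = fit$parameters$variance$sigma)
  }
  for (g in seq_along(params$weights)) {
    params$sigmas[, , g] <- params$sigmas[, , g] + diag(ridge, d)
  }
  structure(c(params, list(kind = "gmm", d = d)),
            class = c("gmm_scorer", "oneclass_scorer"))
}

mvn_log_pdf <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * length(mu) * log(2 * pi)
}

#' Anomaly score of a fitted one-class scorer
#'
#' Uniform orientation across scorers: higher = more abnormal.
#' KDE: negative log-density; OC-SVM: negative decision value;
#' GMM: negative log-likelihood.
#'
#' @param scorer a fitted scorer.
#' @param x probe matrix (`n x d`) or vector.
#' @return Numeric vector of anomaly scores.
#' @export
anomaly_score <- function(scorer, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (inherits(scorer, "kde_scorer")) {
    -kde_log_density(scorer, x)
  } else if (inherits(scorer, "ocsvm_scorer")) {
    dv <- attr(stats::predict(scorer$fit, x, decision.values = TRUE),
               "decision.values")
    -as.numeric(dv)
  } else if (inherits(scorer, "gmm_scorer")) {
    comp <- sapply(seq_along(scorer$weights), function(g) {
      log(scorer$weights[g]) +
        mvn_log_pdf(x, scorer$means[, g], scorer$sigmas[, , g])
    })
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = nrow(x))
    -apply(comp, 1, log_sum_exp)
  } else stop("unknown scorer")
}

#' Score threshold from normal-train scores
#'
#' Nearest-rank quantile of the normal-class training anomaly scores; a
#' probe is called abnormal when its score strictly exceeds the threshold.
#' `q = 1` flags no training point.
#'
#' @param train_scores anomaly scores of the (normal) training set.
#' @param q quantile in (0, 1] (default 0.95).
#' @export
choose_threshold <- function(train_scores, q = 0.95) {
  if (!length(train_scores)) stop("empty scores")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  sort(train_scores)[ceiling(q * length(train_scores))]
}
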