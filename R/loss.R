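#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For a batch of `2N` projection vectors (two views per anchor), rows are
#' L2-normalized internally and the loss is the mean over all `2N` views of
#' `-log( exp(cos(z_i, z_j)/tau) / sum_{k != i} exp(cos(z_i, z_k)/tau) )`,
#' where `j` is the positive partner of view `i`. Every other view in the
#' batch -- including views of instances from other DA distributions -- is
#' a negative.
#'
#' @param z numeric matrix `2N x d` of projections (not necessarily
#'   normalized).
#' @param pair_index integer vector of length `2N`; `pair_index[i]` is the
#'   row of the positive partner of row `i` (an involution without fixed
#'   points).
#' @param temperature softmax temperature `tau` (> 0).
#' @param return_grad also return the gradient with respect to `z`.
#' @return The scalar loss, or `list(loss, grad)` when `return_grad`.
#' @export
nt_xent_loss <- function(z, pair_index, temperature = 0.2,
                         return_grad = FALSE) {
  n2 <- nrow(z)
  if (is.null(n2) || n2 < 4L) stop("need at least 2 anchor pairs (4 views)")
  if (n2 %% 2L != 0L) stop("z must hold an even number of views")
  if (temperature <= 0) stop("temperature must be > 0")
  pair_index <- as.integer(pair_index)
  if (length(pair_index) != n2 || any(pair_index[pair_index] != seq_len(n2)) ||
      any(pair_index == seq_len(n2))) {
    stop("pair_index must be a fixed-point-free involution over rows")
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("zero rows cannot be normalized")
  u <- z / nrm
  s <- tcrossprod(u) / temperature
  diag(s) <- -Inf                       # a view is never its own negative
  lse <- row_log_sum_exp(s)
  pos <- s[cbind(seq_len(n2), pair_index)]
  loss <- mean(lse - pos)
  if (!return_grad) return(loss)

  p <- exp(s - lse)                      # row-softmax over negatives+positive
  g <- p
  g[cbind(seq_len(n2), pair_index)] <- g[cbind(seq_len(n2), pair_index)] - 1
  g <- g / (n2 * temperature)
  du <- (g + t(g)) %*% u                 # d loss / d u  (s = u u' / tau)
  # through the row normalization: du -> dz
  proj <- rowSums(du * u)
  dz <- (du - u * proj) / nrm
  list(loss = loss, grad = dz)
}

# standard two-view pairing: rows 1..N are first views, N+1..2N second views
paired_index <- function(n) c(seq_len(n) + n, seq_len(n))
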