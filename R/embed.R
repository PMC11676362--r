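#' Extract frozen-encoder embeddings for tiles
#'
#' Runs the trained encoder in inference mode (no view transforms, no
#' distribution augmentation) and returns the pre-projection embeddings
#' `h`, one row per tile in input order. Deterministic; batch size does not
#' affect the output.
#'
#' @param checkpoint a [pretrain()] checkpoint (or a bare `cyto_model`).
#' @param tiles list of [tile_record()]s / arrays, or a manifest data frame
#'   with a `path` column of PNG files.
#' @param batch_size tiles per forward pass.
#' @return `n x embedding_dim` matrix; row names are tile identifiers
#'   (paths or indices).
#' @export
embed_tiles <- function(checkpoint, tiles, batch_size = 64L) {
  model <- if (inherits(checkpoint, "cyto_model")) checkpoint else checkpoint$model
  if (is.data.frame(tiles)) {
    paths <- tiles$path
    ids <- paths
    tiles <- lapply(paths, png::readPNG)
  } else {
    ids <- names(tiles) %||% as.character(seq_along(tiles))
  }
  n <- length(tiles)
  if (!n) stop("no tiles to embed")
  xs <- lapply(tiles, tile_to_float)
  sz <- dim(xs[[1]])[1]
  need_mult <- if (model$enc_cfg$architecture == "tiny_cnn") 8L else 32L
  if (sz %% need_mult != 0L) {
    stop(sprintf("tile size %d is not a multiple of %d required by %s",
                 sz, need_mult, model$enc_cfg$architecture))
  }
  out <- matrix(0, n, model$enc_cfg$embedding_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(model$encoder, tiles_to_batch(xs[idx]))
    out[idx, ] <- fw$out
  }
  if (any(!is.finite(out))) stop("non-finite embeddings produced")
  rownames(out) <- ids
  out
}

#' Aggregate tile embeddings into a slide representation
#'
#' @param embeddings `n x d` matrix of the slide's tile embeddings (n >= 1).
#' @param method `"mean"` or `"max"` (element-wise across tiles).
#' @return Numeric vector of length `d`.
#' @export
aggregate_slide <- function(embeddings, method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1)
  if (nrow(embeddings) < 1) stop("empty slide")
  if (method == "mean") colMeans(embeddings) else apply(embeddings, 2, max)
}

#' Aggregate many slides at once
#'
#' @param embeddings tile embedding matrix.
#' @param slide_ids character vector aligned with rows.
#' @param method passed to [aggregate_slide()].
#' @return `n_slides x d` matrix with slide ids as row names.
#' @export
aggregate_slides <- function(embeddings, slide_ids, method = c("mean", "max")) {
  method <- match.arg(method)
  ids <- unique(slide_ids)
  out <- t(vapply(ids, function(s) {
    aggregate_slide(embeddings[slide_ids == s, , drop = FALSE], method)
  }, numeric(ncol(embeddings))))
  rownames(out) <- ids
  out
}
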