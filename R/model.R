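#' Encoder configuration
#'
#' Two encoder families are available: `resnet18` (the fidelity target;
#' 512-dimensional embeddings `h`) and `tiny_cnn`, a four-conv-block
#' encoder with global average pooling (64-dimensional embeddings) suited
#' to CPU-scale experiments. Both are fully convolutional up to the global
#' pooling, so the input size only needs to respect the downsampling
#' factor (a multiple of 8 and at least 16 px for `tiny_cnn`, at least
#' 32 px for `resnet18`).
#'
#' @param architecture `"tiny_cnn"` or `"resnet18"`.
#' @param input_size nominal square input side in pixels.
#' @return An object of class `encoder_config` with the derived
#'   `embedding_dim` (64 or 512).
#' @export
encoder_config <- function(architecture = c("tiny_cnn", "resnet18"),
                           input_size = 32L) {
  architecture <- match.arg(architecture)
  structure(list(
    architecture = architecture,
    input_size = as.integer(input_size),
    embedding_dim = if (architecture == "resnet18") 512L else 64L
  ), class = "encoder_config")
}

#' Projection-head configuration
#'
#' An MLP mapping the embedding `h` to the contrastive space `z`:
#' `n_hidden_layers` linear+ReLU layers of width `hidden_dim` followed by a
#' final linear layer to `output_dim`. The deep (eight-hidden-layer)
#' default follows practice for contrastive one-class pretraining; widths
#' are configurable.
#'
#' @param n_hidden_layers number of hidden layers (>= 1, default 8).
#' @param hidden_dim hidden width (default 512).
#' @param output_dim dimension of `z` (default 128).
#' @export
projection_head_config <- function(n_hidden_layers = 8L, hidden_dim = 512L,
                                   output_dim = 128L) {
  if (n_hidden_layers < 1) stop("n_hidden_layers must be >= 1")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim)),
            class = "projection_head_config")
}

basic_block <- function(c_in, c_out, stride) {
  shortcut <- if (stride != 1L || c_in != c_out) {
    list(layer_conv(c_in, c_out, k = 1L, stride = stride, pad = 0L),
         layer_bn(c_out))
  } else NULL
  layer_residual(
    main = list(layer_conv(c_in, c_out, k = 3L, stride = stride),
                layer_bn(c_out), layer_relu(),
                layer_conv(c_out, c_out, k = 3L), layer_bn(c_out)),
    shortcut = shortcut)
}

build_encoder <- function(cfg) {
  if (cfg$architecture == "tiny_cnn") {
    list(layer_conv(3L, 16L, name = "conv1"), layer_bn(16L),
         layer_relu(name = "relu1"), layer_avgpool2(name = "pool1"),
         layer_conv(16L, 32L, name = "conv2"), layer_bn(32L),
         layer_relu(name = "relu2"), layer_avgpool2(name = "pool2"),
         layer_conv(32L, 64L, name = "conv3"), layer_bn(64L),
         layer_relu(name = "relu3"), layer_avgpool2(name = "pool3"),
         layer_conv(64L, 64L, name = "conv4"), layer_bn(64L),
         layer_relu(name = "relu4"), layer_gap())
  } else {
    layers <- list(layer_conv(3L, 64L, k = 7L, stride = 2L, pad = 3L,
                              name = "conv1"),
                   layer_bn(64L), layer_relu(name = "relu1"),
                   layer_maxpool(3L, 2L, 1L, name = "pool1"))
    plan <- list(c(64L, 64L, 1L), c(64L, 128L, 2L),
                 c(128L, 256L, 2L), c(256L, 512L, 2L))
    for (s in seq_along(plan)) {
      p <- plan[[s]]
      layers <- c(layers, list(
        basic_block(p[1], p[2], p[3]), layer_relu(),
        basic_block(p[2], p[2], 1L),
        layer_relu(name = sprintf("layer%d", s))))
    }
    c(layers, list(layer_gap()))
  }
}

# hidden layers are Linear -> BN -> ReLU, the standard contrastive
# projection-head block; the output layer is a bare linear map.
build_head <- function(d_in, cfg) {
  layers <- list()
  d <- d_in
  for (i in seq_len(cfg$n_hidden_layers)) {
    layers <- c(layers, list(layer_linear(d, cfg$hidden_dim,
                                          name = sprintf("head%d", i)),
                             layer_bn_dense(cfg$hidden_dim),
                             layer_relu()))
    d <- cfg$hidden_dim
  }
  c(layers, list(layer_linear(d, cfg$output_dim, name = "head_out")))
}

#' Build a contrastive model (encoder + projection head)
#'
#' The encoder produces the embedding `h` (the representation used by all
#' downstream scoring); the projection head maps it to `z`, the vector fed
#' to the contrastive loss.
#'
#' @param enc_cfg an [encoder_config()].
#' @param head_cfg a [projection_head_config()].
#' @param seed seed for weight initialization (He).
#' @return An object of class `cyto_model`.
#' @export
build_model <- function(enc_cfg = encoder_config(),
                        head_cfg = projection_head_config(),
                        seed = 1L) {
  with_seed(seed, {
    encoder <- build_encoder(enc_cfg)
    head <- build_head(enc_cfg$embedding_dim, head_cfg)
    structure(list(encoder = encoder, head = head,
                   enc_cfg = enc_cfg, head_cfg = head_cfg),
              class = "cyto_model")
  })
}

# default GradCAM target: output of the last convolutional stage
default_target_layer <- function(model) {
  if (model$enc_cfg$architecture == "tiny_cnn") "relu4" else "layer4"
}

# Stack a list of [0,1] float H x W x 3 arrays into the [H, W, N, C] batch
# layout used by the layer library.
tiles_to_batch <- function(tiles) {
  xs <- lapply(tiles, tile_to_float)
  d <- dim(xs[[1]])
  arr <- array(unlist(xs, use.names = FALSE), c(d[1], d[2], 3L, length(xs)))
  aperm(arr, c(1, 2, 4, 3))
}

#' Forward pass of a contrastive model
#'
#' @param model a [build_model()] object.
#' @param x batch array `[H, W, N, 3]` (see `tiles_to_batch`) or a list of
#'   tiles.
#' @param training training mode (batch statistics for batch norm).
#' @param collect keep per-layer encoder activations (for GradCAM).
#' @return List with `h` (N x embedding_dim), `z` (N x output_dim) and the
#'   layer caches needed for backprop.
#' @keywords internal
model_forward <- function(model, x, training = FALSE, collect = FALSE) {
  if (is.list(x)) x <- tiles_to_batch(x)
  enc <- nn_forward(model$encoder, x, training = training, collect = collect)
  head <- nn_forward(model$head, enc$out, training = training)
  list(h = enc$out, z = head$out, enc = enc, head = head)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the encoder and head weights, the configuration
#' snapshot (encoder, head, training, DA scheme, view transform), the epoch
#' and the loss trace. Serialized with `saveRDS`; a load/save round trip is
#' exact.
#'
#' @param checkpoint a checkpoint list (as produced by [pretrain()]).
#' @param path file path.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck$model, "cyto_model")) stop("not a cytoscreen checkpoint")
  ck
}
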