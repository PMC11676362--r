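#' Training configuration for contrastive pretraining
#'
#' Default recipe: stochastic gradient descent with a single-cycle
#' cosine-annealed learning rate starting at 0.01, batch size 32 anchors,
#' contrastive temperature 0.2, and up to 100 epochs. Desk-scale
#' experiments shrink `max_epochs`.
#'
#' @param lr initial learning rate.
#' @param batch_size anchors per batch (>= 2; each anchor contributes two
#'   views).
#' @param temperature NT-Xent temperature (> 0).
#' @param max_epochs number of passes over the (DA-expanded) instance set.
#' @param momentum SGD momentum.
#' @param seed integer seed governing initialization, shuffling and view
#'   sampling.
#' @export
train_config <- function(lr = 0.01, batch_size = 32L, temperature = 0.2,
                         max_epochs = 100L, momentum = 0.9, seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (batch_size < 2) stop("batch_size must be >= 2 anchor pairs")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 temperature = temperature,
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 seed = as.integer(seed)), class = "train_config")
}

#' Contrastive pretraining on normal-only tiles
#'
#' Expands the dataset across the DA scheme's distributions, then runs
#' SimCLR-style training: per anchor, two stochastic views are drawn and
#' the NT-Xent loss is minimized by SGD with cosine-annealed learning rate.
#' Instances from different DA distributions are distinct anchors and hence
#' mutual negatives. The training set must contain only normal-labeled
#' tiles; any abnormal tile is rejected.
#'
#' @param dataset list of [tile_record()]s (labels checked) or plain
#'   `H x W x 3` arrays (assumed normal).
#' @param scheme a [da_scheme()]. With the color scheme, hue is
#'   automatically excluded from the view-transform color jitter.
#' @param view_cfg a [view_config()].
#' @param enc_cfg an [encoder_config()].
#' @param head_cfg a [projection_head_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A checkpoint list: `model`, `loss_trace` (per-epoch mean loss),
#'   `epoch`, and the configuration snapshot.
#' @export
pretrain <- function(dataset, scheme = da_scheme("none"),
                     view_cfg = view_config(),
                     enc_cfg = encoder_config(),
                     head_cfg = projection_head_config(),
                     train_cfg = train_config(), verbose = FALSE) {
  if (!length(dataset)) stop("empty training dataset")
  labs <- vapply(dataset, function(t)
    if (inherits(t, "tile_record")) t$label else "normal", character(1))
  if (any(labs == "abnormal")) {
    stop("one-class pretraining requires normal-only tiles; found ",
         sum(labs == "abnormal"), " abnormal tile(s)")
  }
  if (scheme$kind == "color") view_cfg$include_hue_in_jitter <- FALSE

  instances <- expand_distribution(dataset, scheme,
                                   seed = derive_seed(train_cfg$seed, 1))
  model <- build_model(enc_cfg, head_cfg, seed = derive_seed(train_cfg$seed, 2))

  n_inst <- length(instances)
  bs <- train_cfg$batch_size
  steps_per_epoch <- max(n_inst %/% bs, 1L)
  total_steps <- steps_per_epoch * train_cfg$max_epochs
  pairs <- NULL
  state_enc <- NULL; state_head <- NULL
  loss_trace <- numeric(train_cfg$max_epochs)
  step <- 0L

  with_seed(derive_seed(train_cfg$seed, 3), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample(n_inst)
      epoch_losses <- numeric(0)
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n_inst)]
        if (length(idx) < 2L) next
        views <- vector("list", 2L * length(idx))
        for (j in seq_along(idx)) {
          px <- instances[[idx[j]]]$pixels
          views[[j]] <- make_view(px, view_cfg)
          views[[length(idx) + j]] <- make_view(px, view_cfg)
        }
        x <- tiles_to_batch(views)
        fw <- model_forward(model, x, training = TRUE)
        if (is.null(pairs) || length(pairs) != 2L * length(idx)) {
          pairs <- paired_index(length(idx))
        }
        lo <- nt_xent_loss(fw$z, pairs, train_cfg$temperature,
                           return_grad = TRUE)
        epoch_losses <- c(epoch_losses, lo$loss)

        bk_head <- nn_backward(model$head, fw$head$caches, lo$grad)
        bk_enc <- nn_backward(model$encoder, fw$enc$caches, bk_head$dx)

        lr_t <- train_cfg$lr * 0.5 * (1 + cos(pi * step / total_steps))
        step <- step + 1L
        up <- nn_sgd_step(model$head, bk_head$grads, state_head, lr_t,
                          train_cfg$momentum)
        model$head <- up$layers; state_head <- up$state
        up <- nn_sgd_step(model$encoder, bk_enc$grads, state_enc, lr_t,
                          train_cfg$momentum)
        model$encoder <- nn_update_bn(up$layers, fw$enc$caches)
        state_enc <- up$state
      }
      loss_trace[epoch] <- mean(epoch_losses)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", epoch,
                        train_cfg$max_epochs, loss_trace[epoch]))
      }
    }
  })
  list(model = model, loss_trace = loss_trace, epoch = train_cfg$max_epochs,
       scheme = scheme, view_cfg = view_cfg, enc_cfg = enc_cfg,
       head_cfg = head_cfg, train_cfg = train_cfg)
}
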