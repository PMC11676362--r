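# Desk-scale study conditions shared by the end-to-end tests: 600 normal
# 32x32 synthetic training tiles, tiny_cnn encoder, 8-hidden-layer
# projection head (width 128 -> 64), SGD lr 0.01 / batch 32 / tau 0.2 with
# cosine annealing. The no-DA model trains 20 epochs; the color-DA model
# trains 7 epochs over its 3x-expanded instance set (compute-matched
# gradient steps). Models are trained once per (scheme, seed) and cached
# for the whole test session.

acc_spec_train <- function(seed) synthetic_spec(tile_size = 32,
                                                seed = 1000L + seed)
acc_spec_test <- function(seed, hue = 0) {
  synthetic_spec(tile_size = 32, seed = 4000L + seed,
                 global_hue_shift_deg = hue)
}

.acc_cache <- new.env(parent = emptyenv())

acc_train_tiles <- function(seed) {
  key <- paste0("tiles", seed)
  if (is.null(.acc_cache[[key]])) {
    .acc_cache[[key]] <- generate_tiles(acc_spec_train(seed), 600, 0)$tiles
  }
  .acc_cache[[key]]
}

acc_model <- function(scheme_kind, seed) {
  key <- paste(scheme_kind, seed, sep = "_")
  if (is.null(.acc_cache[[key]])) {
    epochs <- if (scheme_kind == "color") 7L else 20L
    .acc_cache[[key]] <- pretrain(
      acc_train_tiles(seed), da_scheme(scheme_kind), view_config(),
      encoder_config("tiny_cnn", 32L),
      projection_head_config(8L, 128L, 64L),
      train_config(max_epochs = epochs, seed = seed))
  }
  .acc_cache[[key]]
}

acc_kde <- function(ck, seed) {
  fit_kde(embed_tiles(ck, acc_train_tiles(seed)), 1.0)
}

acc_tile_auc <- function(ck, seed, hue = 0) {
  te <- generate_tiles(acc_spec_test(seed, hue), 100, 100)
  sc <- anomaly_score(acc_kde(ck, seed), embed_tiles(ck, te$tiles))
  auc_score(sc, te$labels)
}
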