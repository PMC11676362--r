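# Small shared fixtures. Heavier trained models live in helper-models.R.

# a flat-color tile (double [0,1])
flat_tile <- function(size, rgb) {
  array(rep(rgb, each = size * size), c(size, size, 3))
}

# deterministic random tile in [0,1]
rand_tile <- function(size, seed = 1) {
  cytoscreen:::with_seed(seed, array(stats::runif(size * size * 3), c(size, size, 3)))
}

# tiny model configs used by fast structural/training tests
tiny_enc <- function(size = 16L) encoder_config("tiny_cnn", size)
tiny_head <- function() projection_head_config(n_hidden_layers = 2L,
                                               hidden_dim = 32L,
                                               output_dim = 16L)

# a quick 3-epoch checkpoint on a handful of tiles (cached per session)
.quick_cache <- new.env(parent = emptyenv())
quick_checkpoint <- function() {
  if (!is.null(.quick_cache$ck)) return(.quick_cache$ck)
  spec <- synthetic_spec(tile_size = 16, seed = 11)
  ds <- generate_tiles(spec, 24, 0)
  ck <- pretrain(ds$tiles, da_scheme("none"), view_config(),
                 tiny_enc(16L), tiny_head(),
                 train_config(max_epochs = 3, batch_size = 8, seed = 5))
  .quick_cache$ck <- ck
  ck
}

# independent oracle: iterative label propagation until fixpoint
propagate_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in 1:h) for (cl in 1:w) {
      if (!mask[r, cl]) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] &&
            lab[rr, cc] < lab[r, cl]) {
          lab[r, cl] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}
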