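# Minimal CNN layer library with manual backpropagation.
#
# Activations are stored as 4-d arrays in [H, W, N, C] order (N = batch).
# That layout lets im2col/col2im run as plain slice-reshape operations with
# no array transposition, which keeps the pure-R training loop fast enough
# for desk-scale experiments. Dense activations are [N, D] matrices.
# Convolution weights are stored as a (k*k*Cin) x Cout matrix whose rows are
# ordered (row-offset fastest, then column-offset, then input channel).

layer_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                       name = NULL) {
  fan_in <- k * k * c_in
  w <- matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), c_in = as.integer(c_in),
       c_out = as.integer(c_out), W = w, b = numeric(c_out), name = name)
}

layer_relu <- function(name = NULL) list(type = "relu", name = name)

layer_avgpool2 <- function(name = NULL) list(type = "avgpool2", name = name)

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L, name = NULL) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), name = name)
}

layer_gap <- function(name = "gap") list(type = "gap", name = name)

layer_linear <- function(d_in, d_out, name = NULL) {
  w <- matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out)
  list(type = "linear", W = w, b = numeric(d_out), name = name)
}

layer_bn <- function(c, eps = 1e-5, momentum = 0.1, name = NULL) {
  list(type = "bn", c = as.integer(c), gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c),
       eps = eps, momentum = momentum, name = name)
}

layer_residual <- function(main, shortcut = NULL, name = NULL) {
  list(type = "residual", main = main, shortcut = shortcut, name = name)
}

# batch norm over the batch dimension of an [N, D] dense activation
layer_bn_dense <- function(d, eps = 1e-5, momentum = 0.1, name = NULL) {
  list(type = "bn_dense", d = as.integer(d), gamma = rep(1, d),
       beta = numeric(d), running_mean = numeric(d), running_var = rep(1, d),
       eps = eps, momentum = momentum, name = name)
}

bn_dense_forward <- function(layer, x, training) {
  n <- nrow(x)
  res <- .bn_fwd_cpp(x, n, ncol(x), layer$gamma, layer$beta,
                     layer$running_mean, layer$running_var, layer$eps,
                     training)
  out <- res$out; dim(out) <- dim(x)
  list(out = out, cache = list(xhat = res$xhat, inv = res$inv,
                               mu = res$mu, v = res$v, n = n,
                               dims = dim(x)))
}

bn_dense_backward <- function(layer, cache, dy) {
  res <- .bn_bwd_cpp(cache$xhat, cache$inv, layer$gamma, dy,
                     cache$n, cache$dims[2])
  dx <- res$dx; dim(dx) <- cache$dims
  list(dx = dx, grads = list(gamma = res$dgamma, beta = res$dbeta))
}

pad_hw <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

conv_forward <- function(layer, x) {
  res <- .conv_fwd_cpp(x, dim(x), layer$W, layer$b, layer$k, layer$stride,
                       layer$pad)
  list(out = res$out,
       cache = list(m = res$M, in_dim = dim(x), ho = res$ho, wo = res$wo))
}

conv_backward <- function(layer, cache, dy) {
  res <- .conv_bwd_cpp(cache$m, layer$W, dy, cache$in_dim, layer$k,
                       layer$stride, layer$pad, cache$ho, cache$wo)
  list(dx = res$dx, grads = list(W = res$dW, b = res$db))
}

# Pure-R reference implementations of the convolution forward/backward,
# kept as the independent oracle for the compiled kernels.
conv_forward_ref <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; ci <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  xp <- pad_hw(x, p)
  ho <- (h + 2L * p - k) %/% s + 1L
  wo <- (w + 2L * p - k) %/% s + 1L
  m <- matrix(0, ho * wo * n, k * k * ci)
  cseq <- seq_len(ci)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ridx <- seq.int(di, by = s, length.out = ho)
    cidx <- seq.int(dj, by = s, length.out = wo)
    sl <- xp[ridx, cidx, , , drop = FALSE]
    dim(sl) <- c(ho * wo * n, ci)
    m[, (cseq - 1L) * (k * k) + (dj - 1L) * k + di] <- sl
  }
  y <- m %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  dim(y) <- c(ho, wo, n, layer$c_out)
  list(out = y, cache = list(m = m, in_dim = d, ho = ho, wo = wo))
}

conv_backward_ref <- function(layer, cache, dy) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]; n <- d[3]; ci <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  ho <- cache$ho; wo <- cache$wo
  dim(dy) <- c(ho * wo * n, layer$c_out)
  dw <- crossprod(cache$m, dy)
  db <- colSums(dy)
  dm <- tcrossprod(dy, layer$W)
  dxp <- array(0, c(h + 2L * p, w + 2L * p, n, ci))
  cseq <- seq_len(ci)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ridx <- seq.int(di, by = s, length.out = ho)
    cidx <- seq.int(dj, by = s, length.out = wo)
    blk <- dm[, (cseq - 1L) * (k * k) + (dj - 1L) * k + di, drop = FALSE]
    dim(blk) <- c(ho, wo, n, ci)
    dxp[ridx, cidx, , ] <- dxp[ridx, cidx, , , drop = FALSE] + blk
  }
  dx <- if (p > 0L) dxp[(p + 1):(p + h), (p + 1):(p + w), , , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dw, b = db))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; ci <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  xp <- pad_hw(x, p, fill = -Inf)
  ho <- (h + 2L * p - k) %/% s + 1L
  wo <- (w + 2L * p - k) %/% s + 1L
  best <- array(-Inf, c(ho, wo, n, ci))
  arg <- array(1L, c(ho, wo, n, ci))
  idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    ridx <- seq.int(di, by = s, length.out = ho)
    cidx <- seq.int(dj, by = s, length.out = wo)
    sl <- xp[ridx, cidx, , , drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    arg[upd] <- idx
  }
  list(out = best, cache = list(arg = arg, in_dim = d, ho = ho, wo = wo))
}

maxpool_backward <- function(layer, cache, dy) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]; n <- d[3]; ci <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  ho <- cache$ho; wo <- cache$wo
  dxp <- array(0, c(h + 2L * p, w + 2L * p, n, ci))
  idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    ridx <- seq.int(di, by = s, length.out = ho)
    cidx <- seq.int(dj, by = s, length.out = wo)
    contrib <- dy * (cache$arg == idx)
    dxp[ridx, cidx, , ] <- dxp[ridx, cidx, , , drop = FALSE] + contrib
  }
  if (p > 0L) dxp[(p + 1):(p + h), (p + 1):(p + w), , , drop = FALSE] else dxp
}

bn_stats_forward <- function(layer, x, training) {
  d <- dim(x)
  m <- d[1] * d[2] * d[3]
  res <- .bn_fwd_cpp(x, m, d[4], layer$gamma, layer$beta,
                     layer$running_mean, layer$running_var, layer$eps,
                     training)
  out <- res$out; dim(out) <- d
  list(out = out, cache = list(xhat = res$xhat, inv = res$inv,
                               mu = res$mu, v = res$v, d = d))
}

bn_backward <- function(layer, cache, dy) {
  d <- cache$d
  m <- d[1] * d[2] * d[3]
  res <- .bn_bwd_cpp(cache$xhat, cache$inv, layer$gamma, dy, m, d[4])
  dx <- res$dx; dim(dx) <- d
  list(dx = dx, grads = list(gamma = res$dgamma, beta = res$dbeta))
}

# Forward through a list of layers. Returns the output plus per-layer caches
# (inputs/masks needed for the backward pass) and, when `collect` is TRUE,
# each layer's output activation (used by GradCAM to reach a named layer).
nn_forward <- function(layers, x, training = FALSE, collect = FALSE) {
  caches <- vector("list", length(layers))
  outs <- if (collect) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = conv_forward(l, x),
      relu = {
        mask <- x > 0
        list(out = x * mask, cache = list(mask = mask))
      },
      avgpool2 = {
        d <- dim(x)
        o1 <- seq.int(1L, d[1], by = 2L); o2 <- seq.int(2L, d[1], by = 2L)
        p1 <- seq.int(1L, d[2], by = 2L); p2 <- seq.int(2L, d[2], by = 2L)
        y <- (x[o1, p1, , , drop = FALSE] + x[o2, p1, , , drop = FALSE] +
              x[o1, p2, , , drop = FALSE] + x[o2, p2, , , drop = FALSE]) / 4
        list(out = y, cache = list(in_dim = d))
      },
      maxpool = maxpool_forward(l, x),
      gap = {
        d <- dim(x)
        xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
        y <- matrix(colMeans(xm), d[3], d[4])
        list(out = y, cache = list(in_dim = d))
      },
      linear = {
        y <- x %*% l$W
        y <- y + rep(l$b, each = nrow(y))
        list(out = y, cache = list(x = x))
      },
      bn = bn_stats_forward(l, x, training),
      bn_dense = bn_dense_forward(l, x, training),
      residual = {
        main <- nn_forward(l$main, x, training)
        short <- if (is.null(l$shortcut)) list(out = x, caches = NULL) else
          nn_forward(l$shortcut, x, training)
        list(out = main$out + short$out,
             cache = list(main = main$caches, shortcut = short$caches))
      },
      stop("unknown layer type: ", l$type))
    caches[[i]] <- res$cache
    x <- res$out
    if (collect) outs[[i]] <- x
  }
  list(out = x, caches = caches, outs = outs)
}

# Backward through a list of layers from gradient `dy` at the output.
# `stop_at` (layer index) stops early and returns the gradient with respect
# to that layer's OUTPUT (used by GradCAM); 0 means full backward.
nn_backward <- function(layers, caches, dy, stop_at = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i == stop_at) {
      return(list(dx = dy, grads = grads, stopped = TRUE))
    }
    l <- layers[[i]]
    cache <- caches[[i]]
    if (l$type == "conv") {
      res <- conv_backward(l, cache, dy)
      dy <- res$dx; grads[[i]] <- res$grads
    } else if (l$type == "relu") {
      dy <- dy * cache$mask
    } else if (l$type == "avgpool2") {
      d <- cache$in_dim
      dx <- array(0, d)
      q <- dy / 4
      o1 <- seq.int(1L, d[1], by = 2L); o2 <- seq.int(2L, d[1], by = 2L)
      p1 <- seq.int(1L, d[2], by = 2L); p2 <- seq.int(2L, d[2], by = 2L)
      dx[o1, p1, , ] <- q; dx[o2, p1, , ] <- q
      dx[o1, p2, , ] <- q; dx[o2, p2, , ] <- q
      dy <- dx
    } else if (l$type == "maxpool") {
      dy <- maxpool_backward(l, cache, dy)
    } else if (l$type == "gap") {
      d <- cache$in_dim
      hw <- d[1] * d[2]
      dx <- matrix(rep(as.vector(dy) / hw, each = hw), hw, d[3] * d[4])
      dim(dx) <- d
      dy <- dx
    } else if (l$type == "linear") {
      grads[[i]] <- list(W = crossprod(cache$x, dy), b = colSums(dy))
      dy <- tcrossprod(dy, l$W)
    } else if (l$type == "bn") {
      res <- bn_backward(l, cache, dy)
      dy <- res$dx; grads[[i]] <- res$grads
    } else if (l$type == "bn_dense") {
      res <- bn_dense_backward(l, cache, dy)
      dy <- res$dx; grads[[i]] <- res$grads
    } else if (l$type == "residual") {
      main <- nn_backward(l$main, cache$main, dy)
      short_dx <- if (is.null(l$shortcut)) dy else {
        res <- nn_backward(l$shortcut, cache$shortcut, dy)
        grads[[i]]$shortcut <- res$grads
        res$dx
      }
      grads[[i]] <- list(main = main$grads,
                         shortcut = grads[[i]]$shortcut)
      dy <- main$dx + short_dx
    }
  }
  list(dx = dy, grads = grads, stopped = FALSE)
}

# Update batch-norm running statistics after a training forward pass.
nn_update_bn <- function(layers, caches) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("bn", "bn_dense")) {
      m <- l$momentum
      layers[[i]]$running_mean <- (1 - m) * l$running_mean + m * caches[[i]]$mu
      layers[[i]]$running_var <- (1 - m) * l$running_var + m * caches[[i]]$v
    } else if (l$type == "residual") {
      layers[[i]]$main <- nn_update_bn(l$main, caches[[i]]$main)
      if (!is.null(l$shortcut)) {
        layers[[i]]$shortcut <- nn_update_bn(l$shortcut, caches[[i]]$shortcut)
      }
    }
  }
  layers
}

# SGD with momentum over the (possibly nested) layer structure.
# `state` mirrors the parameter structure; pass NULL on the first step.
nn_sgd_step <- function(layers, grads, state, lr, momentum = 0.9) {
  if (is.null(state)) state <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "residual") {
      sub <- nn_sgd_step(l$main, g$main, state[[i]]$main, lr, momentum)
      layers[[i]]$main <- sub$layers
      st <- list(main = sub$state)
      if (!is.null(l$shortcut) && !is.null(g$shortcut)) {
        sub2 <- nn_sgd_step(l$shortcut, g$shortcut, state[[i]]$shortcut,
                            lr, momentum)
        layers[[i]]$shortcut <- sub2$layers
        st$shortcut <- sub2$state
      }
      state[[i]] <- st
    } else {
      st <- state[[i]]
      for (p in names(g)) {
        v <- if (is.null(st[[p]])) g[[p]] * 0 else st[[p]]
        v <- momentum * v + g[[p]]
        layers[[i]][[p]] <- l[[p]] - lr * v
        st[[p]] <- v
      }
      state[[i]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Index of a named layer within a flat layer list.
nn_layer_index <- function(layers, name) {
  nm <- vapply(layers, function(l) l$name %||% "", character(1))
  i <- match(name, nm)
  if (is.na(i)) stop("unknown layer name: ", name,
                     " (available: ", paste(nm[nzchar(nm)], collapse = ", "), ")")
  i
}
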