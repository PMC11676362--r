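# Layer-level checks of the compiled kernels and the backward pass.

test_that("compiled convolution matches the pure-R reference", {
  cases <- list(c(k = 3, s = 1, p = 1), c(k = 3, s = 2, p = 1),
                c(k = 1, s = 2, p = 0), c(k = 7, s = 2, p = 3))
  for (cs in cases) {
    l <- cytoscreen:::with_seed(cs[["k"]] * 10 + cs[["s"]],
      cytoscreen:::layer_conv(4L, 6L, cs[["k"]], cs[["s"]], cs[["p"]]))
    x <- cytoscreen:::with_seed(1, array(stats::rnorm(15 * 11 * 3 * 4),
                                         c(15, 11, 3, 4)))
    f_cpp <- cytoscreen:::conv_forward(l, x)
    f_ref <- cytoscreen:::conv_forward_ref(l, x)
    expect_equal(f_cpp$out, f_ref$out, tolerance = 1e-12)
    dy <- cytoscreen:::with_seed(2, array(stats::rnorm(length(f_cpp$out)),
                                          dim(f_cpp$out)))
    b_cpp <- cytoscreen:::conv_backward(l, f_cpp$cache, dy)
    b_ref <- cytoscreen:::conv_backward_ref(l, f_ref$cache, dy)
    expect_equal(b_cpp$dx, b_ref$dx, tolerance = 1e-12)
    expect_equal(unname(b_cpp$grads$W), unname(b_ref$grads$W),
                 tolerance = 1e-10)
    expect_equal(as.numeric(b_cpp$grads$b), as.numeric(b_ref$grads$b),
                 tolerance = 1e-10)
  }
})

# finite-difference check of d(sum(out * probe)) / d(param or input)
fd_layer_check <- function(layers, x, n_probe = 6, tol = 1e-4) {
  fw <- cytoscreen:::nn_forward(layers, x, training = TRUE)
  probe <- cytoscreen:::with_seed(99, array(stats::rnorm(length(fw$out)),
                                            dim(fw$out) %||% length(fw$out)))
  bk <- cytoscreen:::nn_backward(layers, fw$caches, probe)
  eps <- 1e-5
  loss_at <- function(ls, xx) sum(cytoscreen:::nn_forward(ls, xx,
                                                          training = TRUE)$out * probe)
  # input gradient
  idx <- cytoscreen:::with_seed(5, sample(length(x), n_probe))
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (loss_at(layers, xp) - loss_at(layers, xm)) / (2 * eps)
    expect_equal(bk$dx[i], fd, tolerance = tol)
  }
  # parameter gradients of the first parameterized layer
  for (li in seq_along(layers)) {
    g <- bk$grads[[li]]
    if (is.null(g) || is.null(g$W %||% g$gamma)) next
    pname <- if (!is.null(g$W)) "W" else "gamma"
    pm <- layers[[li]][[pname]]
    idx <- cytoscreen:::with_seed(6, sample(length(pm), min(n_probe, length(pm))))
    for (i in idx) {
      lp <- layers; lp[[li]][[pname]][i] <- pm[i] + eps
      lm <- layers; lm[[li]][[pname]][i] <- pm[i] - eps
      fd <- (loss_at(lp, x) - loss_at(lm, x)) / (2 * eps)
      expect_equal(g[[pname]][i], fd, tolerance = tol)
    }
    break
  }
}

test_that("backward pass matches finite differences through conv stacks", {
  `%||%` <- cytoscreen:::`%||%`
  layers <- cytoscreen:::with_seed(3, list(
    cytoscreen:::layer_conv(3L, 4L), cytoscreen:::layer_relu(),
    cytoscreen:::layer_avgpool2(),
    cytoscreen:::layer_conv(4L, 5L), cytoscreen:::layer_relu(),
    cytoscreen:::layer_gap(),
    cytoscreen:::layer_linear(5L, 3L)))
  x <- cytoscreen:::with_seed(4, array(stats::rnorm(8 * 8 * 2 * 3),
                                       c(8, 8, 2, 3)))
  fd_layer_check(layers, x)
})

test_that("backward pass matches finite differences through resnet blocks", {
  `%||%` <- cytoscreen:::`%||%`
  layers <- cytoscreen:::with_seed(8, list(
    cytoscreen:::layer_conv(3L, 4L, k = 3L, stride = 2L),
    cytoscreen:::layer_bn(4L), cytoscreen:::layer_relu(),
    cytoscreen:::layer_maxpool(3L, 2L, 1L),
    cytoscreen:::basic_block(4L, 8L, 2L), cytoscreen:::layer_relu(),
    cytoscreen:::layer_gap()))
  x <- cytoscreen:::with_seed(9, array(stats::rnorm(16 * 16 * 2 * 3),
                                       c(16, 16, 2, 3)))
  fd_layer_check(layers, x, tol = 5e-4)
})

test_that("encoders produce the documented embedding dimensions", {
  tiny <- build_model(encoder_config("tiny_cnn", 16L), tiny_head(), seed = 1)
  fw <- cytoscreen:::model_forward(tiny, list(rand_tile(16, 1)))
  expect_equal(dim(fw$h), c(1L, 64L))
  expect_equal(dim(fw$z), c(1L, 16L))

  rn <- build_model(encoder_config("resnet18", 32L),
                    projection_head_config(8L, 64L, 32L), seed = 1)
  fw2 <- cytoscreen:::model_forward(rn, list(rand_tile(32, 2)))
  expect_equal(dim(fw2$h), c(1L, 512L))

  # projection head structure: n_hidden + 1 linear layers
  n_lin <- sum(vapply(tiny$head, function(l) l$type == "linear", logical(1)))
  expect_equal(n_lin, tiny$head_cfg$n_hidden_layers + 1L)
  expect_error(encoder_config("vgg"), "arg")
})
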