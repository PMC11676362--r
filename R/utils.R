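# Internal helpers shared across modules: seeded evaluation, color-space
# conversion, and image resampling primitives.

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched. All user-facing stochastic functions route through this so a
# given seed is reproducible regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed, kept inside 32-bit signed range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 7919) %% 2147483629
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

#' @noRd
assert_rgb <- function(x, what = "tile") {
  if (!is_rgb_array(x)) {
    stop(sprintf("%s must be an H x W x 3 array", what), call. = FALSE)
  }
  invisible(x)
}

# Convert 8-bit integer pixels (0..255) to double [0,1]; pass doubles through.
tile_to_float <- function(x) {
  if (inherits(x, "tile_record")) x <- x$pixels
  assert_rgb(x)
  if (is.double(x) && max(x) <= 1 + 1e-9) return(clamp01(x))
  x / 255
}

# Quantize double [0,1] pixels to 8-bit integers.
tile_to_int <- function(x) {
  assert_rgb(x)
  storage <- as.integer(round(clamp01(x) * 255))
  array(storage, dim = dim(x))
}

# Rec. 601 grayscale luminance on the [0,1] scale.
luminance <- function(x) {
  x <- tile_to_float(x)
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# --- HSV <-> RGB on flat channel vectors in [0,1] (hue as fraction of a turn)

rgb_to_hsv_mat <- function(x) {
  # x: H x W x 3 double in [0,1]; returns 3 x n matrix (h, s, v)
  n <- prod(dim(x)[1:2])
  m <- rbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

hsv_to_rgb_arr <- function(hsv, dims) {
  h6 <- (hsv[1, ] %% 1) * 6
  s <- clamp01(hsv[2, ])
  v <- clamp01(hsv[3, ])
  f <- function(n) {
    k <- (n + h6) %% 6
    v - v * s * pmax(pmin(k, 4 - k, 1), 0)
  }
  array(c(f(5), f(3), f(1)), dim = dims)
}

# --- resampling ---------------------------------------------------------

# Bilinear resize of an H x W (x C) image to out_h x out_w using
# half-pixel-centre sampling with edge clamping.
bilinear_resize <- function(x, out_h, out_w) {
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(dim(x), 1L))
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  if (h == out_h && w == out_w) {
    return(if (single) x[, , 1] else x)
  }
  sy <- h / out_h
  sx <- w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy + 0.5  # source row coordinate (1-based)
  xc <- (seq_len(out_w) - 0.5) * sx + 0.5
  y0 <- pmin(pmax(floor(yc), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xc), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, nc))
  for (c in seq_len(nc)) {
    ch <- x[, , c]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    d <- ch[y1, x0, drop = FALSE]; e <- ch[y1, x1, drop = FALSE]
    top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
    bot <- d * (1 - wx)[col(d)] + e * wx[col(e)]
    out[, , c] <- top * (1 - wy)[row(top)] + bot * wy[row(bot)]
  }
  if (single) out[, , 1] else out
}

# Separable Gaussian blur with reflective padding; kernel size odd.
gaussian_blur <- function(x, sigma, kernel_size) {
  if (sigma <= 0) return(x)
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(dim(x), 1L))
  k <- as.integer(kernel_size)
  if (k %% 2L == 0L) k <- k + 1L
  r <- (k - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  refl <- function(idx, n) {
    idx <- abs(idx - 1) + 1          # reflect below
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    pmin(pmax(idx, 1), n)
  }
  out <- x
  for (c in seq_len(nc)) {
    ch <- x[, , c]
    tmp <- matrix(0, h, w)
    for (o in -r:r) tmp <- tmp + g[o + r + 1] * ch[refl(seq_len(h) + o, h), , drop = FALSE]
    res <- matrix(0, h, w)
    for (o in -r:r) res <- res + g[o + r + 1] * tmp[, refl(seq_len(w) + o, w), drop = FALSE]
    out[, , c] <- res
  }
  if (single) out[, , 1] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
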