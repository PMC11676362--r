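#' Distribution-augmentation scheme
#'
#' Distribution augmentation (DA) expands a one-class training set with
#' transformed copies, each copy treated as a distinct distribution (and
#' hence a distinct anchor in the contrastive loss). Two schemes are
#' supported: `color` (per-copy hue rotation drawn from one of several hue
#' intervals, in degrees) and `rotation` (exact right-angle rotations).
#'
#' @param kind `"none"`, `"color"` or `"rotation"`.
#' @param hue_intervals_deg list of `(lo, hi)` hue intervals in degrees for
#'   the color scheme; reversed bounds are normalized. Defaults to
#'   `(-16, 16)`, `(-16, -12)`, `(12, 16)`.
#' @param angles_deg rotation angles for the rotation scheme; multiples of
#'   90, `0` serving as the identity distribution.
#' @return An object of class `da_scheme`.
#' @export
da_scheme <- function(kind = c("none", "color", "rotation"),
                      hue_intervals_deg = list(c(-16, 16), c(-16, -12), c(12, 16)),
                      angles_deg = c(0, 90, 180, 270)) {
  kind <- match.arg(kind)
  hue_intervals_deg <- lapply(hue_intervals_deg, function(iv) {
    if (length(iv) != 2) stop("hue intervals must have two bounds")
    sort(iv)
  })
  if (kind == "color" && !length(hue_intervals_deg)) {
    stop("color scheme needs at least one hue interval")
  }
  if (any(angles_deg %% 90 != 0)) stop("angles must be multiples of 90")
  structure(list(kind = kind, hue_intervals_deg = hue_intervals_deg,
                 angles_deg = angles_deg), class = "da_scheme")
}

#' Number of distributions in a DA scheme
#' @param scheme a [da_scheme()].
#' @export
n_distributions <- function(scheme) {
  switch(scheme$kind,
         none = 1L,
         color = length(scheme$hue_intervals_deg),
         rotation = length(scheme$angles_deg))
}

#' Exact right-angle tile rotation
#'
#' Lossless (pixel-permutation) rotation; positive angles rotate
#' counter-clockwise. Under 90 degrees a pixel at 0-based `(x, y)` maps to
#' `(H - 1 - y, x)`.
#'
#' @param tile square H x W x 3 array (or H x W matrix).
#' @param angle one of 0, 90, 180, 270 (mod 360).
#' @return Rotated array of the same type.
#' @export
rotate_tile <- function(tile, angle) {
  if (angle %% 90 != 0) stop("angle must be a multiple of 90")
  k <- (as.integer(angle) %/% 90L) %% 4L
  if (k == 0L) return(tile)
  rot1 <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # 90 deg CCW
  rot <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(tile)) return(rot(tile))
  assert_rgb(tile)
  out <- array(tile[1], dim = dim(tile))
  for (c in 1:3) out[, , c] <- rot(tile[, , c])
  out
}

#' Hue rotation of an RGB tile
#'
#' Rotates the HSV hue channel by `delta_deg` (wrapping at 360), leaving
#' saturation and value untouched up to 8-bit rounding. Gray pixels
#' (saturation 0) are unchanged.
#'
#' @param tile H x W x 3 array, 8-bit or double in [0, 1].
#' @param delta_deg hue shift in degrees, in (-180, 180].
#' @return Tile of the same storage type.
#' @export
hue_shift <- function(tile, delta_deg) {
  rec <- inherits(tile, "tile_record")
  px <- if (rec) tile$pixels else tile
  assert_rgb(px)
  was_int <- !(is.double(px) && max(px) <= 1 + 1e-9)
  x <- tile_to_float(px)
  if (delta_deg %% 360 != 0) {
    hsv <- rgb_to_hsv_mat(x)
    hsv[1, ] <- (hsv[1, ] + delta_deg / 360) %% 1
    x <- hsv_to_rgb_arr(hsv, dim(x))
  }
  out <- if (was_int) tile_to_int(x) else x
  if (rec) { tile$pixels <- out; tile } else out
}

#' Per-view transform configuration
#'
#' Parameters of the stochastic view transformation applied independently
#' to each of the two views of an anchor: random resized crop, random
#' horizontal flip, color jitter, random grayscale, Gaussian blur -- in
#' that order. Following common contrastive-pretraining practice, a jitter
#' strength `s` means brightness/contrast/saturation factors drawn within
#' `0.8 s` of 1 and a hue shift within `0.2 s` turns; the Gaussian-blur
#' kernel is 10% of the tile side (odd-rounded). When the color DA scheme
#' is active the hue component is excluded from the jitter
#' (`include_hue_in_jitter = FALSE`).
#'
#' @param jitter_strength color-jitter strength (default 0.4).
#' @param include_hue_in_jitter include the hue component in color jitter.
#' @param crop_scale area-fraction range of the random resized crop.
#' @param crop_ratio aspect-ratio range of the crop.
#' @param flip_prob probability of a horizontal flip.
#' @param jitter_prob probability of applying color jitter.
#' @param grayscale_prob probability of grayscale conversion.
#' @param blur_sigma range of the Gaussian-blur sigma (pixels).
#' @param blur_prob probability of applying the blur.
#' @return An object of class `view_config`.
#' @export
view_config <- function(jitter_strength = 0.4, include_hue_in_jitter = TRUE,
                        crop_scale = c(0.2, 1), crop_ratio = c(3 / 4, 4 / 3),
                        flip_prob = 0.5, jitter_prob = 0.8,
                        grayscale_prob = 0.2, blur_sigma = c(0.1, 2),
                        blur_prob = 0.5) {
  stopifnot(jitter_strength >= 0,
            all(c(flip_prob, jitter_prob, grayscale_prob, blur_prob) >= 0),
            all(c(flip_prob, jitter_prob, grayscale_prob, blur_prob) <= 1))
  structure(list(jitter_strength = jitter_strength,
                 include_hue_in_jitter = include_hue_in_jitter,
                 crop_scale = crop_scale, crop_ratio = crop_ratio,
                 flip_prob = flip_prob, jitter_prob = jitter_prob,
                 grayscale_prob = grayscale_prob, blur_sigma = blur_sigma,
                 blur_prob = blur_prob), class = "view_config")
}

#' Expand a dataset across DA distributions
#'
#' Produces `|dataset| x n_distributions` augmented instances, each tagged
#' with the index of the distribution it belongs to (`da_label`, 1-based).
#' For the color scheme the hue shift of each instance is drawn uniformly
#' within its interval; rotations are exact. `kind = "none"` is the
#' identity (all instances carry `da_label = 1`).
#'
#' @param dataset list of [tile_record()]s or H x W x 3 arrays (or the
#'   `tiles` element of [generate_tiles()]).
#' @param scheme a [da_scheme()].
#' @param seed integer seed for the hue draws.
#' @return List of instances: `list(pixels, da_label, source_id)` with
#'   pixels as double [0, 1] arrays.
#' @export
expand_distribution <- function(dataset, scheme = da_scheme("none"), seed = 1L) {
  if (!length(dataset)) stop("dataset is empty")
  nd <- n_distributions(scheme)
  with_seed(seed, {
    out <- vector("list", length(dataset) * nd)
    k <- 0L
    for (i in seq_along(dataset)) {
      x <- tile_to_float(dataset[[i]])
      for (d in seq_len(nd)) {
        px <- switch(scheme$kind,
          none = x,
          rotation = rotate_tile(x, scheme$angles_deg[d]),
          color = {
            iv <- scheme$hue_intervals_deg[[d]]
            hue_shift(x, stats::runif(1, iv[1], iv[2]))
          })
        k <- k + 1L
        out[[k]] <- list(pixels = px, da_label = d, source_id = i)
      }
    }
    out
  })
}

# color jitter sub-operations on a float tile
adjust_brightness <- function(x, f) clamp01(x * f)
adjust_contrast <- function(x, f) {
  m <- mean(luminance(x))
  clamp01((x - m) * f + m)
}
adjust_saturation <- function(x, f) {
  g <- luminance(x)
  gray <- array(rep(g, 3), dim(x))
  clamp01(gray + (x - gray) * f)
}

#' Draw one stochastic view of a tile
#'
#' Applies, in order: random resized crop (resized back to the input size,
#' bilinear), random horizontal flip, color jitter
#' (brightness/contrast/saturation and optionally hue), random grayscale
#' conversion, and Gaussian blur. With all probabilities 0, `crop_scale`
#' and `crop_ratio` fixed at 1 and strength 0 the view is the identity.
#'
#' @param tile [tile_record()] or H x W x 3 array.
#' @param config a [view_config()].
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (the mode used inside the training loop).
#' @return Double [0, 1] array of the input's spatial size.
#' @export
make_view <- function(tile, config = view_config(), seed = NULL) {
  x <- tile_to_float(tile)
  run <- function() {
    h <- dim(x)[1]; w <- dim(x)[2]
    # random resized crop
    area <- stats::runif(1, config$crop_scale[1], config$crop_scale[2]) * h * w
    aspect <- exp(stats::runif(1, log(config$crop_ratio[1]),
                               log(config$crop_ratio[2])))
    cw <- min(max(round(sqrt(area * aspect)), 1), w)
    ch <- min(max(round(sqrt(area / aspect)), 1), h)
    oy <- if (h > ch) sample.int(h - ch + 1L, 1L) - 1L else 0L
    ox <- if (w > cw) sample.int(w - cw + 1L, 1L) - 1L else 0L
    if (ch != h || cw != w || oy != 0L || ox != 0L) {
      x <- x[(oy + 1):(oy + ch), (ox + 1):(ox + cw), , drop = FALSE]
      x <- bilinear_resize(x, h, w)
    }
    if (stats::runif(1) < config$flip_prob) x <- x[, w:1, , drop = FALSE]
    if (stats::runif(1) < config$jitter_prob && config$jitter_strength > 0) {
      s <- config$jitter_strength
      x <- adjust_brightness(x, stats::runif(1, max(0, 1 - 0.8 * s), 1 + 0.8 * s))
      x <- adjust_contrast(x, stats::runif(1, max(0, 1 - 0.8 * s), 1 + 0.8 * s))
      x <- adjust_saturation(x, stats::runif(1, max(0, 1 - 0.8 * s), 1 + 0.8 * s))
      if (config$include_hue_in_jitter) {
        x <- hue_shift(x, stats::runif(1, -0.2 * s, 0.2 * s) * 360)
      }
    }
    if (stats::runif(1) < config$grayscale_prob) {
      g <- luminance(x)
      x <- array(rep(g, 3), dim(x))
    }
    if (stats::runif(1) < config$blur_prob) {
      sigma <- stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
      ksize <- max(3L, as.integer(round(0.1 * h)))
      x <- gaussian_blur(x, sigma, ksize)
    }
    clamp01(x)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
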