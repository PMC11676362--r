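#' Specification for the synthetic cytology tile generator
#'
#' Describes the geometry and staining statistics of generated tiles. Cells
#' are drawn as a pale cytoplasm ellipse containing a darker nucleus
#' ellipse; abnormal cells carry a much larger nucleus-to-cytoplasm (N:C)
#' area ratio, a darker nucleus, and a sinusoidally perturbed (irregular)
#' nuclear boundary -- the morphological cues used to call high-grade
#' squamous lesions. A global hue rotation emulates a staining batch effect
#' between datasets.
#'
#' @param tile_size tile side in pixels (>= 16; 64 default, 256 supported).
#' @param n_cells_mean expected number of cells per tile (shifted Poisson,
#'   at least one cell unless 0 is forced).
#' @param abnormal_nc_ratio_range,normal_nc_ratio_range intervals of the
#'   nucleus-to-cytoplasm area ratio for abnormal / normal cells; non-empty
#'   sub-intervals of (0, 1].
#' @param nucleus_darkening multiplier on the HSV value channel of abnormal
#'   nuclei (hyperchromasia).
#' @param boundary_irregularity radial perturbation amplitude of abnormal
#'   nuclear boundaries, as a fraction of the nuclear radius.
#' @param global_hue_shift_deg hue rotation in degrees applied to the whole
#'   tile after drawing (staining batch effect; 0 = none).
#' @param background_luminance background brightness in [0, 1].
#' @param seed integer seed; identical spec + seed reproduce tiles
#'   bit-identically.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(tile_size = 64,
                           n_cells_mean = 3,
                           abnormal_nc_ratio_range = c(0.4, 0.8),
                           normal_nc_ratio_range = c(0.05, 0.15),
                           nucleus_darkening = 0.6,
                           boundary_irregularity = 0.3,
                           global_hue_shift_deg = 0,
                           background_luminance = 245 / 255,
                           seed = 1L) {
  check_ratio <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] <= 0 || r[2] > 1) {
      stop(sprintf("%s must be a non-empty sub-interval of (0, 1]", what),
           call. = FALSE)
    }
  }
  if (tile_size < 16) stop("tile_size must be >= 16", call. = FALSE)
  check_ratio(abnormal_nc_ratio_range, "abnormal_nc_ratio_range")
  check_ratio(normal_nc_ratio_range, "normal_nc_ratio_range")
  structure(list(
    tile_size = as.integer(tile_size),
    n_cells_mean = n_cells_mean,
    abnormal_nc_ratio_range = abnormal_nc_ratio_range,
    normal_nc_ratio_range = normal_nc_ratio_range,
    nucleus_darkening = nucleus_darkening,
    boundary_irregularity = boundary_irregularity,
    global_hue_shift_deg = global_hue_shift_deg,
    background_luminance = background_luminance,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Draw one cell onto the canvas (in place via return). px/py are pixel-centre
# coordinate grids. Returns list(canvas, box or NULL, nc_ratio).
draw_cell <- function(canvas, px, py, spec, abnormal) {
  ts <- spec$tile_size
  cx <- stats::runif(1, 0.15 * ts, 0.85 * ts)
  cy <- stats::runif(1, 0.15 * ts, 0.85 * ts)
  r0 <- ts * stats::runif(1, 0.12, 0.20)
  a <- r0 * stats::runif(1, 0.9, 1.3)
  b <- r0^2 / a
  phi <- stats::runif(1, 0, pi)
  cphi <- cos(phi); sphi <- sin(phi)

  rng <- if (abnormal) spec$abnormal_nc_ratio_range else spec$normal_nc_ratio_range
  nc_ratio <- stats::runif(1, rng[1], rng[2])
  rn0 <- sqrt(nc_ratio * a * b)
  an <- rn0 * stats::runif(1, 0.9, 1.15)
  bn <- rn0^2 / an
  # nucleus centre offset, kept inside the cytoplasm
  off <- stats::runif(1, 0, 0.3) * max(a - an, 0)
  oang <- stats::runif(1, 0, 2 * pi)
  ncx <- cx + off * cos(oang)
  ncy <- cy + off * sin(oang)

  # cytoplasm color: pale pink (majority) or pale cyan, HSV
  pink <- stats::runif(1) < 0.7
  cyto_h <- if (pink) 0.87 + stats::runif(1, -0.03, 0.03) else 0.52 + stats::runif(1, -0.03, 0.03)
  cyto_s <- stats::runif(1, 0.12, 0.28)
  cyto_v <- stats::runif(1, 0.86, 0.95)
  nuc_h <- 0.75 + stats::runif(1, -0.03, 0.03)
  nuc_s <- stats::runif(1, 0.45, 0.65)
  nuc_v <- stats::runif(1, 0.45, 0.60)
  lobes <- sample(3:7, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  if (abnormal) {
    nuc_v <- nuc_v * spec$nucleus_darkening
    nuc_s <- min(nuc_s + 0.1, 1)
  }

  # cytoplasm mask (rotated ellipse)
  dx <- px - cx; dy <- py - cy
  u <- dx * cphi + dy * sphi
  v <- -dx * sphi + dy * cphi
  cyto <- (u / a)^2 + (v / b)^2 <= 1

  # nucleus mask, with radial sinusoidal boundary perturbation when abnormal
  dxn <- px - ncx; dyn <- py - ncy
  un <- dxn * cphi + dyn * sphi
  vn <- -dxn * sphi + dyn * cphi
  rho <- sqrt((un / an)^2 + (vn / bn)^2)
  if (abnormal && spec$boundary_irregularity > 0) {
    theta <- atan2(vn, un)
    lim <- 1 + spec$boundary_irregularity * sin(lobes * theta + phase)
  } else {
    lim <- 1
  }
  nuc <- (rho <= lim) & cyto

  cyto_rgb <- hsv_to_rgb_arr(rbind(cyto_h, cyto_s, cyto_v), c(1, 1, 3))
  nuc_rgb <- hsv_to_rgb_arr(rbind(nuc_h, nuc_s, nuc_v), c(1, 1, 3))
  for (ch in 1:3) {
    plane <- canvas[, , ch]
    plane[cyto] <- cyto_rgb[1, 1, ch]
    plane[nuc] <- nuc_rgb[1, 1, ch]
    canvas[, , ch] <- plane
  }

  box <- NULL
  if (abnormal) {
    hw <- sqrt((a * cphi)^2 + (b * sphi)^2)
    hh <- sqrt((a * sphi)^2 + (b * cphi)^2)
    x0 <- max(floor(cx - hw), 0); x1 <- min(ceiling(cx + hw), spec$tile_size)
    y0 <- max(floor(cy - hh), 0); y1 <- min(ceiling(cy + hh), spec$tile_size)
    if (x1 > x0 && y1 > y0) box <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  }
  list(canvas = canvas, box = box, nc_ratio = nc_ratio)
}

#' Generate one synthetic cytology tile
#'
#' Paints a near-white background, a shifted-Poisson number of cells (later
#' cells painted over earlier ones), and finally applies the spec's global
#' hue shift before 8-bit quantization. Abnormal tiles contain at least one
#' abnormal cell; every abnormal cell is annotated with the tight bounding
#' box of its cytoplasm ellipse (0-based, half-open pixel coordinates).
#'
#' @param spec a [synthetic_spec()].
#' @param cls `"normal"` or `"abnormal"`.
#' @param seed integer seed for this tile (defaults to `spec$seed`).
#' @return A list with `tile` (a `tile_record`, 8-bit RGB pixels), `boxes`
#'   (data frame `x0, y0, x1, y1, label`; zero rows for normal tiles) and
#'   `geometry` (per-cell N:C ratios and abnormality flags).
#' @export
generate_tile <- function(spec, cls = c("normal", "abnormal"), seed = spec$seed) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  cls <- match.arg(cls)
  ts <- spec$tile_size
  with_seed(seed, {
    n_cells <- if (spec$n_cells_mean == 0) 0L else
      1L + stats::rpois(1, max(spec$n_cells_mean - 1, 0))

    # background with a touch of texture
    bg_v <- clamp01(spec$background_luminance +
                      stats::rnorm(ts * ts, 0, 0.008))
    canvas <- hsv_to_rgb_arr(
      rbind(rep(0.9, ts * ts), rep(0.02, ts * ts), bg_v), c(ts, ts, 3))

    px <- matrix(rep(seq_len(ts) - 0.5, each = ts), ts, ts)  # x = column
    py <- matrix(rep(seq_len(ts) - 0.5, times = ts), ts, ts) # y = row

    boxes <- list()
    nc_ratios <- numeric(0)
    abn_flags <- logical(0)
    if (n_cells > 0) {
      abn <- if (cls == "abnormal") {
        flags <- stats::runif(n_cells) < 0.4
        flags[1] <- TRUE
        flags
      } else rep(FALSE, n_cells)
      for (i in seq_len(n_cells)) {
        res <- draw_cell(canvas, px, py, spec, abn[i])
        canvas <- res$canvas
        nc_ratios <- c(nc_ratios, res$nc_ratio)
        abn_flags <- c(abn_flags, abn[i])
        if (!is.null(res$box)) boxes[[length(boxes) + 1L]] <- res$box
      }
    }

    canvas <- canvas + array(stats::rnorm(ts * ts * 3, 0, 0.006), dim(canvas))
    canvas <- clamp01(canvas)
    if (spec$global_hue_shift_deg != 0) {
      canvas <- hue_shift(canvas, spec$global_hue_shift_deg)
    }

    boxes_df <- if (length(boxes)) {
      df <- as.data.frame(do.call(rbind, boxes))
      df$label <- "abnormal"
      df
    } else {
      data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
                 y1 = integer(0), label = character(0))
    }
    list(
      tile = tile_record(tile_to_int(canvas), label = cls),
      boxes = boxes_df,
      geometry = data.frame(cell = seq_along(nc_ratios),
                            abnormal = abn_flags, nc_ratio = nc_ratios)
    )
  })
}

#' Generate a set of synthetic tiles in memory
#'
#' @inheritParams generate_tile
#' @param n_normal,n_abnormal tile counts (>= 0).
#' @return A list with `tiles` (list of `tile_record`), `boxes` (list of box
#'   data frames, aligned), `labels`, and `geometry`.
#' @export
generate_tiles <- function(spec, n_normal, n_abnormal) {
  if (n_normal < 0 || n_abnormal < 0) stop("counts must be >= 0")
  labels <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  tiles <- vector("list", length(labels))
  boxes <- vector("list", length(labels))
  geom <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    res <- generate_tile(spec, labels[i], seed = derive_seed(spec$seed, i))
    res$tile$slide_id <- "synthetic"
    tiles[[i]] <- res$tile
    boxes[[i]] <- res$boxes
    geom[[i]] <- res$geometry
  }
  list(tiles = tiles, boxes = boxes, labels = labels,
       geometry = do.call(rbind, geom))
}

#' Generate a synthetic tile dataset on disk
#'
#' Writes 8-bit RGB PNG tiles, one JSON box file per tile, and a manifest
#' CSV (`path, label, slide_id, fold`). Re-running with the same spec/seed
#' reproduces identical files byte for byte.
#'
#' @inheritParams generate_tiles
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_dataset <- function(spec, n_normal, n_abnormal, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set <- generate_tiles(spec, n_normal, n_abnormal)
  n <- length(set$tiles)
  paths <- file.path(dir, sprintf("tile_%05d.png", seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(tile_to_float(set$tiles[[i]]$pixels), paths[i])
    bx <- set$boxes[[i]]
    jsonlite::write_json(
      bx[, c("x0", "y0", "x1", "y1", "label")],
      sub("\\.png$", ".json", paths[i]),
      dataframe = "rows", auto_unbox = FALSE)
  }
  manifest <- data.frame(path = paths, label = set$labels,
                         slide_id = "synthetic", fold = NA_integer_,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate a synthetic slide set
#'
#' Normal slides contain only normal tiles; abnormal slides contain
#' `ceiling(abnormal_tile_fraction * tiles_per_slide)` abnormal tiles.
#'
#' @inheritParams generate_tile
#' @param n_normal_slides,n_abnormal_slides slide counts.
#' @param tiles_per_slide tiles per slide (>= 1).
#' @param abnormal_tile_fraction fraction in (0, 1] of abnormal tiles on an
#'   abnormal slide.
#' @param dir optional output directory; when `NULL` tiles are kept in
#'   memory.
#' @return A list with `manifest` (tile-level data frame: `slide_id,
#'   slide_label, label, path` or index) and `tiles` (list of `tile_record`,
#'   when in memory).
#' @export
generate_slide_set <- function(spec, n_normal_slides, n_abnormal_slides,
                               tiles_per_slide, abnormal_tile_fraction = 0.3,
                               dir = NULL) {
  if (tiles_per_slide < 1) stop("tiles_per_slide must be >= 1")
  if (n_abnormal_slides > 0 &&
      (abnormal_tile_fraction <= 0 || abnormal_tile_fraction > 1)) {
    stop("abnormal_tile_fraction must be in (0, 1]")
  }
  slide_labels <- c(rep("normal", n_normal_slides),
                    rep("abnormal", n_abnormal_slides))
  n_ab_tiles <- ceiling(abnormal_tile_fraction * tiles_per_slide)
  rows <- list(); tiles <- list(); k <- 0L
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(slide_labels)) {
    sid <- sprintf("slide_%03d", s)
    lab <- slide_labels[s]
    tile_labels <- if (lab == "normal") rep("normal", tiles_per_slide) else
      c(rep("abnormal", n_ab_tiles), rep("normal", tiles_per_slide - n_ab_tiles))
    for (t in seq_len(tiles_per_slide)) {
      k <- k + 1L
      res <- generate_tile(spec, tile_labels[t],
                           seed = derive_seed(spec$seed, s * 100000 + t))
      res$tile$slide_id <- sid
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("%s_tile_%04d.png", sid, t))
        png::writePNG(tile_to_float(res$tile$pixels), path)
      } else {
        tiles[[k]] <- res$tile
      }
      rows[[k]] <- data.frame(slide_id = sid, slide_label = lab,
                              label = tile_labels[t], path = path,
                              index = k, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "slides.csv"), row.names = FALSE)
  }
  list(manifest = manifest, tiles = if (is.null(dir)) tiles else NULL)
}
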