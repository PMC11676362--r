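#' Tile record
#'
#' Lightweight container for one tile: 8-bit RGB pixels, slide provenance,
#' the tile's 0-based top-left origin `(x, y)` in its source raster, and a
#' class label.
#'
#' @param pixels H x W x 3 array (8-bit integers 0..255 or doubles in
#'   [0, 1], stored as given).
#' @param slide_id slide identifier.
#' @param origin integer `(x, y)` top-left position in the source raster
#'   (after any downsampling), 0-based.
#' @param label one of `"normal"`, `"abnormal"`, `"unlabeled"`.
#' @export
tile_record <- function(pixels, slide_id = NA_character_,
                        origin = c(0L, 0L), label = "unlabeled") {
  assert_rgb(pixels)
  if (!label %in% c("normal", "abnormal", "unlabeled")) {
    stop("label must be normal/abnormal/unlabeled")
  }
  structure(list(pixels = pixels, slide_id = slide_id,
                 origin = as.integer(origin), label = label),
            class = "tile_record")
}

#' @export
print.tile_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tile_record %dx%d label=%s slide=%s origin=(%d,%d)>\n",
              d[1], d[2], x$label, x$slide_id, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Read an RGB raster from PNG or TIFF
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return H x W x 3 double array in [0, 1].
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else stop("unsupported raster format: ", ext)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3]
  x
}

# factor-of-n area (block-mean) downsampling; trailing rows/cols beyond the
# largest multiple of the factor are dropped.
downsample_raster <- function(raster, factor) {
  if (factor == 1) return(raster)
  f <- as.integer(factor)
  h <- (dim(raster)[1] %/% f) * f
  w <- (dim(raster)[2] %/% f) * f
  raster <- raster[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, c(h %/% f, w %/% f, dim(raster)[3]))
  for (i in seq_len(f)) for (j in seq_len(f)) {
    out <- out + raster[seq(i, h, by = f), seq(j, w, by = f), , drop = FALSE]
  }
  out / f^2
}

#' Cut a raster into square tiles
#'
#' Optionally downsamples by an integer factor (area averaging), then crops
#' a grid of `tile_size` tiles starting at origin (0, 0). Partial edge tiles
#' are discarded. With the default `stride = tile_size` the grid is
#' non-overlapping.
#'
#' @param raster H x W x 3 array (double [0,1] or 8-bit).
#' @param tile_size tile side in pixels (default 256).
#' @param stride grid step in pixels.
#' @param downsample_factor integer downsampling factor (2 halves the
#'   resolution, e.g. 0.25 to 0.5 um/pixel).
#' @param slide_id provenance carried onto each tile.
#' @return List of [tile_record()]s; empty (with a warning) if the raster is
#'   smaller than one tile after downsampling.
#' @export
tile_raster <- function(raster, tile_size = 256, stride = tile_size,
                        downsample_factor = 1, slide_id = NA_character_) {
  assert_rgb(raster, "raster")
  raster <- downsample_raster(raster, downsample_factor)
  h <- dim(raster)[1]; w <- dim(raster)[2]
  if (h < tile_size || w < tile_size) {
    warning("raster smaller than one tile; returning no tiles")
    return(list())
  }
  ys <- seq(0L, h - tile_size, by = stride)
  xs <- seq(0L, w - tile_size, by = stride)
  tiles <- vector("list", length(ys) * length(xs))
  k <- 0L
  for (y in ys) for (x in xs) {
    k <- k + 1L
    tiles[[k]] <- tile_record(
      raster[(y + 1):(y + tile_size), (x + 1):(x + tile_size), , drop = FALSE],
      slide_id = slide_id, origin = c(x, y))
  }
  tiles
}

#' Fraction of background pixels in a tile
#'
#' A pixel counts as background when its Rec. 601 grayscale luminance is at
#' least `luminance_threshold` (white liquid-based-cytology background).
#'
#' @param tile a [tile_record()] or H x W x 3 array.
#' @param luminance_threshold default 230/255.
#' @return Fraction in [0, 1].
#' @export
background_fraction <- function(tile, luminance_threshold = 230 / 255) {
  mean(luminance(if (inherits(tile, "tile_record")) tile$pixels else tile) >=
         luminance_threshold)
}

#' Exclude background-dominated (and, optionally, artifact) tiles
#'
#' Drops tiles whose background fraction strictly exceeds `max_background`
#' (a tile at exactly the cap is retained). `artifact_hook` is an optional
#' user predicate, `function(tile) TRUE/FALSE`, returning `TRUE` for tiles
#' to exclude; no artifact detector is shipped.
#'
#' @param tiles list of tiles.
#' @param max_background background-fraction cap (default 0.5).
#' @param artifact_hook optional predicate; `TRUE` = artifact, excluded.
#' @param luminance_threshold passed to [background_fraction()].
#' @return The retained tiles, in input order.
#' @export
filter_tiles <- function(tiles, max_background = 0.5, artifact_hook = NULL,
                         luminance_threshold = 230 / 255) {
  keep <- vapply(tiles, function(t) {
    if (background_fraction(t, luminance_threshold) > max_background) return(FALSE)
    if (!is.null(artifact_hook) && isTRUE(artifact_hook(t))) return(FALSE)
    TRUE
  }, logical(1))
  tiles[keep]
}

# clipped half-open box around a nucleus centre
center_box <- function(cx, cy, size, raster_w = Inf, raster_h = Inf) {
  half <- size / 2
  c(x0 = max(cx - half, 0), y0 = max(cy - half, 0),
    x1 = min(cx + half, raster_w), y1 = min(cy + half, raster_h))
}

#' Label grid tiles from nucleus-centred cell annotations
#'
#' Annotations are nucleus-centred square boxes (90 x 90 px by default).
#' A tile is labeled `abnormal` when at least one abnormal-class box centre
#' falls inside it. Otherwise it is labeled `normal` only when the summed
#' area of abnormal-class boxes intersecting it is below
#' `normal_area_cap` x tile area; tiles in between are `unlabeled` and
#' dropped by default.
#'
#' @param tiles list of [tile_record()]s carrying origins in raster
#'   coordinates.
#' @param boxes data frame with columns `x_center, y_center, class` (raster
#'   coordinates, same frame as the tile origins).
#' @param abnormal_classes character vector of abnormal class strings (e.g.
#'   `c("HSIL", "ASC-H")`).
#' @param normal_classes character vector of the remaining known classes;
#'   any class outside both sets is an error naming the offenders.
#' @param normal_area_cap area fraction cap for the normal label (default
#'   0.05).
#' @param box_size annotation box side in pixels (default 90).
#' @param raster_dim optional `(width, height)` used to clip annotation
#'   boxes at the raster bounds.
#' @param drop_unlabeled drop tiles labeled neither normal nor abnormal
#'   (default `TRUE`).
#' @return Tiles with labels assigned.
#' @export
label_tiles_from_boxes <- function(tiles, boxes, abnormal_classes,
                                   normal_classes = character(0),
                                   normal_area_cap = 0.05, box_size = 90,
                                   raster_dim = NULL,
                                   drop_unlabeled = TRUE) {
  known <- c(abnormal_classes, normal_classes)
  bad <- setdiff(unique(boxes$class), known)
  if (length(bad)) {
    stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  }
  rw <- if (is.null(raster_dim)) Inf else raster_dim[1]
  rh <- if (is.null(raster_dim)) Inf else raster_dim[2]
  ab <- boxes[boxes$class %in% abnormal_classes, , drop = FALSE]
  ab_boxes <- if (nrow(ab)) t(mapply(center_box, ab$x_center, ab$y_center,
                                     MoreArgs = list(size = box_size,
                                                     raster_w = rw,
                                                     raster_h = rh)))
              else matrix(numeric(0), 0, 4)

  out <- lapply(tiles, function(tl) {
    ts <- dim(tl$pixels)[1]
    tx0 <- tl$origin[1]; ty0 <- tl$origin[2]
    tx1 <- tx0 + ts; ty1 <- ty0 + ts
    if (nrow(ab)) {
      center_in <- ab$x_center >= tx0 & ab$x_center < tx1 &
                   ab$y_center >= ty0 & ab$y_center < ty1
      if (any(center_in)) {
        tl$label <- "abnormal"
        return(tl)
      }
      iw <- pmax(pmin(ab_boxes[, 3], tx1) - pmax(ab_boxes[, 1], tx0), 0)
      ih <- pmax(pmin(ab_boxes[, 4], ty1) - pmax(ab_boxes[, 2], ty0), 0)
      frac <- sum(iw * ih) / (ts * ts)
      tl$label <- if (frac < normal_area_cap) "normal" else "unlabeled"
    } else {
      tl$label <- "normal"
    }
    tl
  })
  if (drop_unlabeled) {
    out <- out[vapply(out, function(t) t$label != "unlabeled", logical(1))]
  }
  out
}

#' Balance a manifest to equal class counts
#'
#' Randomly subsamples the majority class, without replacement, to match the
#' minority-class count; the minority class is kept untouched.
#'
#' @param manifest data frame with a `label` column (`normal`/`abnormal`).
#' @param seed integer seed.
#' @return Balanced manifest (original row order preserved).
#' @export
balance_classes <- function(manifest, seed = 1L) {
  counts <- table(factor(manifest$label, levels = c("normal", "abnormal")))
  if (any(counts == 0)) stop("both classes must be present")
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(c("normal", "abnormal"), minority)
  n_min <- min(counts)
  maj_idx <- which(manifest$label == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, n_min)))
  manifest[sort(c(which(manifest$label == minority), keep_maj)), , drop = FALSE]
}

#' Assign cross-validation folds
#'
#' Produces `k` disjoint validation folds covering every row once. With
#' `group_by_slide = TRUE` (default) whole slides are assigned to folds
#' (greedily, largest slide first, to the currently smallest fold) so that
#' no slide straddles a fold boundary.
#'
#' @param manifest data frame; needs a `slide_id` column when grouping.
#' @param k number of folds (>= 2; default 4 for 75/25 splits).
#' @param group_by_slide keep all tiles of a slide in one fold.
#' @param seed integer seed.
#' @return The manifest with an integer `fold` column in `1..k`.
#' @export
make_folds <- function(manifest, k = 4, group_by_slide = TRUE, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  n <- nrow(manifest)
  if (group_by_slide) {
    if (is.null(manifest$slide_id)) stop("manifest needs a slide_id column")
    slides <- unique(manifest$slide_id)
    if (length(slides) < k) stop("fewer slides than folds")
    sizes <- table(manifest$slide_id)[slides]
    ord <- with_seed(seed, sample(seq_along(slides)))
    slides <- slides[ord]; sizes <- as.integer(sizes[ord])
    ord2 <- order(-sizes)
    fold_of <- integer(length(slides))
    load <- numeric(k)
    for (i in ord2) {
      f <- which.min(load)
      fold_of[i] <- f
      load[f] <- load[f] + sizes[i]
    }
    manifest$fold <- fold_of[match(manifest$slide_id, slides)]
  } else {
    if (n < k) stop("fewer rows than folds")
    perm <- with_seed(seed, sample(n))
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k), n)
    manifest$fold <- fold
  }
  manifest
}

#' Load tiles listed in a manifest
#'
#' Reads the PNG tiles of a manifest data frame (or manifest CSV path) into
#' [tile_record()]s, carrying labels and slide ids.
#'
#' @param manifest data frame with `path`, `label`, `slide_id` columns, or
#'   the path of such a CSV.
#' @return List of [tile_record()]s in manifest row order.
#' @export
load_tiles <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(manifest$path[i])
    tile_record(tile_to_int(px),
                slide_id = manifest$slide_id[i] %||% NA_character_,
                label = manifest$label[i] %||% "unlabeled")
  })
}
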