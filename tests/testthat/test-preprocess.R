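test_that("grid tiling yields the expected tile counts and origins", {
  big <- cytoscreen:::with_seed(2, array(stats::runif(1020 * 1376 * 3),
                                         c(1020, 1376, 3)))
  tiles <- tile_raster(big, tile_size = 256)
  expect_length(tiles, 15L)                 # floor(1376/256) x floor(1020/256)
  expect_equal(tiles[[1]]$origin, c(0L, 0L))
  expect_equal(tiles[[15]]$origin, c(4L * 256L, 2L * 256L))

  one <- tile_raster(rand_tile(256, 3), tile_size = 256)
  expect_length(one, 1L)
  expect_equal(one[[1]]$origin, c(0L, 0L))

  ds <- tile_raster(rand_tile(512, 4), tile_size = 256, downsample_factor = 2)
  expect_length(ds, 1L)
  expect_equal(dim(ds[[1]]$pixels)[1:2], c(256L, 256L))

  expect_warning(small <- tile_raster(rand_tile(128, 5), tile_size = 256),
                 "smaller")
  expect_length(small, 0L)
})

test_that("tiling is lossless over the covered grid", {
  r <- cytoscreen:::with_seed(7, array(stats::runif(512 * 768 * 3),
                                       c(512, 768, 3)))
  tiles <- tile_raster(r, tile_size = 256)
  rec <- array(0, dim(r))
  for (t in tiles) {
    x <- t$origin[1]; y <- t$origin[2]
    rec[(y + 1):(y + 256), (x + 1):(x + 256), ] <- t$pixels
  }
  expect_identical(rec, r)
})

test_that("background fraction and the strict >50% exclusion rule", {
  white <- flat_tile(16, c(1, 1, 1))
  black <- flat_tile(16, c(0, 0, 0))
  expect_equal(background_fraction(white), 1.0)
  expect_equal(background_fraction(black), 0.0)

  half <- black; half[1:8, , ] <- 1
  expect_equal(background_fraction(half), 0.5)

  just_over <- black
  just_over[1:8, , ] <- 1
  just_over[9, 1:9, ] <- 1   # 128 + 9 of 256 pixels -> 53.5%
  tiles <- list(white, half, just_over, black)
  kept <- filter_tiles(tiles)
  expect_length(kept, 2L)           # half retained (tie), white+51% dropped
  expect_identical(kept[[1]], half)

  # idempotence and the artifact hook
  expect_identical(filter_tiles(kept), kept)
  expect_length(filter_tiles(tiles, artifact_hook = function(t) TRUE), 0L)
})

test_that("box-based labeling follows the centre and 5%-area rules", {
  t256 <- tile_record(array(0.5, c(256, 256, 3)), origin = c(0L, 0L))

  # centre inside -> abnormal
  b1 <- data.frame(x_center = 128, y_center = 128, class = "HSIL")
  lab <- label_tiles_from_boxes(list(t256), b1, abnormal_classes = "HSIL")
  expect_equal(lab[[1]]$label, "abnormal")

  # centre outside, overlap 44x90 = 3960 px^2 = 6.0% >= 5% -> not normal
  b2 <- data.frame(x_center = 257, y_center = 128, class = "HSIL")
  lab2 <- label_tiles_from_boxes(list(t256), b2, abnormal_classes = "HSIL",
                                 drop_unlabeled = FALSE)
  expect_equal(lab2[[1]]$label, "unlabeled")
  expect_length(label_tiles_from_boxes(list(t256), b2,
                                       abnormal_classes = "HSIL"), 0L)

  # centre outside, small overlap: width 256-241=15, height 50 -> 750 px^2
  # = 1.1% of the tile < 5% -> normal
  b3 <- data.frame(x_center = 286, y_center = 5, class = "HSIL")
  lab3 <- label_tiles_from_boxes(list(t256), b3, abnormal_classes = "HSIL")
  expect_equal(lab3[[1]]$label, "normal")

  # no boxes at all -> normal
  lab4 <- label_tiles_from_boxes(list(t256),
                                 data.frame(x_center = numeric(0),
                                            y_center = numeric(0),
                                            class = character(0)),
                                 abnormal_classes = "HSIL")
  expect_equal(lab4[[1]]$label, "normal")

  # unknown class -> error naming the offender
  b5 <- data.frame(x_center = 1, y_center = 1, class = "MYSTERY")
  expect_error(label_tiles_from_boxes(list(t256), b5,
                                      abnormal_classes = "HSIL",
                                      normal_classes = "NILM"),
               "MYSTERY")

  # labeling independent of box ordering
  many <- data.frame(x_center = c(10, 257, 128), y_center = c(400, 128, 128),
                     class = "HSIL")
  l_a <- label_tiles_from_boxes(list(t256), many, abnormal_classes = "HSIL",
                                drop_unlabeled = FALSE)
  l_b <- label_tiles_from_boxes(list(t256), many[3:1, ],
                                abnormal_classes = "HSIL",
                                drop_unlabeled = FALSE)
  expect_equal(l_a[[1]]$label, l_b[[1]]$label)
})

test_that("class balancing subsamples the majority without replacement", {
  man <- data.frame(path = sprintf("t%04d", 1:(5746 + 2628)),
                    label = c(rep("normal", 5746), rep("abnormal", 2628)))
  bal <- balance_classes(man, seed = 4)
  expect_equal(as.vector(table(bal$label)[c("normal", "abnormal")]),
               c(2628L, 2628L))
  expect_true(all(man$path[man$label == "abnormal"] %in% bal$path))
  expect_false(any(duplicated(bal$path)))
  expect_identical(balance_classes(man, seed = 4), bal)

  eq <- man[c(1:5, 5747:5751), ]
  expect_identical(balance_classes(eq, seed = 1), eq)
  expect_error(balance_classes(man[1:3, ], seed = 1), "both classes")
})

test_that("fold assignment partitions rows and can group by slide", {
  man <- data.frame(id = 1:8, label = "normal", slide_id = rep("s", 8))
  f <- make_folds(man, k = 4, group_by_slide = FALSE, seed = 1)
  expect_equal(sort(unique(f$fold)), 1:4)
  expect_equal(as.vector(table(f$fold)), rep(2L, 4))

  man2 <- data.frame(id = 1:12, slide_id = rep(c("a", "b", "c", "d"), each = 3))
  g <- make_folds(man2, k = 4, group_by_slide = TRUE, seed = 2)
  per_slide_folds <- tapply(g$fold, g$slide_id, function(x) length(unique(x)))
  expect_true(all(per_slide_folds == 1))
  expect_equal(as.vector(table(g$fold)), rep(3L, 4))

  expect_error(make_folds(data.frame(slide_id = c("a", "a", "b")), k = 4),
               "fewer")
  expect_identical(make_folds(man2, k = 4, seed = 9),
                   make_folds(man2, k = 4, seed = 9))
})
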