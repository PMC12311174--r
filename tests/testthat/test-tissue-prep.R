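test_that("thumbnail extraction does ceiling arithmetic and preserves content", {
  img <- array(stats::runif(2240 * 2240 * 3), dim = c(2240, 2240, 3))
  th <- extract_thumbnail(img, 10)
  expect_equal(dim(th)[1:2], c(224, 224))
  expect_identical(dim(extract_thumbnail(img, 1)), dim(img))
  rect <- array(0.5, dim = c(448, 224, 3))
  expect_equal(dim(extract_thumbnail(rect, 2))[1:2], c(224, 112))
  expect_error(extract_thumbnail(array(0, dim = c(0, 5, 3))), "empty")
})

test_that("sharpness filter drops uniform images and honors degenerate thresholds", {
  flat <- matrix(0.5, 64, 64)
  expect_false(any(blur_mask(flat, sigma = 2, threshold = 1e-6)))
  expect_true(all(blur_mask(flat, sigma = 2, threshold = 0)))
})

test_that("texture filter separates flat background from noise", {
  flat <- matrix(0.96, 64, 64)
  expect_false(any(flat_mask(flat, window = 5, flat_tol = 0.01)))
  noisy <- matrix(stats::runif(64 * 64), 64, 64)
  expect_true(all(flat_mask(noisy, window = 5, flat_tol = 0.01)))
})

test_that("planted blur patch is dropped while sharp tissue is kept", {
  sl <- gen_synthetic_slide(synth_slide_spec(seed = 12))
  th <- extract_thumbnail(sl$image, 2)
  keep <- blur_mask(th, sigma = 1.5, threshold = 0.09 * diff(range((th[,,1]+th[,,2]+th[,,3])/3)))
  down <- function(m) as.matrix(EBImage::resize(m * 1, w = nrow(keep), h = ncol(keep))) >= 0.5
  gt_blur <- down(sl$masks$blur)
  gt_tissue <- down(sl$masks$tissue)
  expect_lt(mean(keep[gt_blur]), 0.10)      # >= 90% of blur pixels dropped
  expect_gt(mean(keep[gt_tissue]), 0.90)    # <= 10% of sharp tissue dropped
})

test_that("morphological refinement removes islands, fills holes, keeps boundary case", {
  m <- matrix(FALSE, 20, 20)
  m[5, 5] <- TRUE
  expect_false(any(refine_mask(m, min_object = 10, max_hole = 0)))

  ring <- matrix(FALSE, 20, 20)
  ring[8:12, 8:12] <- TRUE
  ring[9:11, 9:11] <- FALSE  # 9-px hole
  filled <- refine_mask(ring, min_object = 1, max_hole = 10)
  expect_true(all(filled[8:12, 8:12]))

  # component exactly at min_object is retained (>= rule)
  m2 <- matrix(FALSE, 20, 20)
  m2[1:3, 1:3] <- TRUE  # 9 pixels
  expect_true(any(refine_mask(m2, min_object = 9, max_hole = 0)))
  expect_false(any(refine_mask(m2, min_object = 10, max_hole = 0)))
})

test_that("fat and dark artifact heuristics remove planted regions only", {
  sl <- gen_synthetic_slide(synth_slide_spec(seed = 5))
  th <- extract_thumbnail(sl$image, 2)
  down <- function(m) as.matrix(EBImage::resize(m * 1, w = dim(th)[1], h = dim(th)[2])) >= 0.5
  full <- matrix(TRUE, dim(th)[1], dim(th)[2])
  out <- remove_fat_and_dark(full, th)
  gt_dark <- down(sl$masks$dark)
  gt_fat <- down(sl$masks$fat)
  gt_tissue <- down(sl$masks$tissue)
  expect_lt(mean(out[gt_dark]), 0.05)
  expect_lt(mean(out[gt_fat]), 0.05)
  # mid-intensity textured tissue untouched
  expect_gt(mean(out[gt_tissue]), 0.95)
  expect_error(remove_fat_and_dark(matrix(TRUE, 3, 3), th), "dimensions")
})

test_that("mask chain logs stages and only fill_holes adds pixels", {
  sl <- gen_synthetic_slide(synth_slide_spec(seed = 8))
  tm <- build_tissue_mask(extract_thumbnail(sl$image, 2))
  expect_s3_class(tm, "tissue_mask")
  expect_equal(tm$stage_log$stage,
               c("blur", "flat", "remove_small_objects", "fill_holes",
                 "fat_dark", "edge_trim"))
  adding <- tm$stage_log$delta_pixels > 0
  expect_true(all(tm$stage_log$stage[adding] == "fill_holes"))

  # blank slide: empty mask but a complete stage log
  blank <- gen_synthetic_slide(synth_slide_spec(width = 128, height = 128,
                                                tissue_blobs = 0, blur_patches = 0,
                                                dark_labels = 0, fat_holes = 0,
                                                seed = 1))
  tm0 <- build_tissue_mask(extract_thumbnail(blank$image, 2))
  expect_equal(sum(tm0$mask), 0)
  expect_gt(nrow(tm0$stage_log), 0)
})

test_that("final mask recovers planted tissue and rejects artifacts", {
  res <- t(vapply(21:23, function(s) {
    sl <- gen_synthetic_slide(synth_slide_spec(seed = s))
    tm <- build_tissue_mask(extract_thumbnail(sl$image, 2))
    down <- function(m) as.matrix(EBImage::resize(m * 1, w = nrow(tm$mask),
                                                  h = ncol(tm$mask))) >= 0.5
    gt <- lapply(sl$masks, down)
    c(jaccard = sum(tm$mask & gt$tissue) / sum(tm$mask | gt$tissue),
      blur = sum(tm$mask & gt$blur) / max(1, sum(gt$blur)),
      dark = sum(tm$mask & gt$dark) / max(1, sum(gt$dark)),
      fat = sum(tm$mask & gt$fat) / max(1, sum(gt$fat)))
  }, c(jaccard = 0, blur = 0, dark = 0, fat = 0)))
  expect_true(all(res[, "jaccard"] >= 0.8))
  expect_true(all(res[, c("blur", "dark", "fat")] < 0.10))
})

test_that("tiling emits the analytic grid and respects coverage exactly", {
  tm <- structure(list(mask = matrix(TRUE, 112, 112), scale = 4,
                       stage_log = NULL), class = "tissue_mask")
  expect_equal(nrow(tile_slide(tm, c(448, 448), 224, 0.5)$coords), 4)
  # upper bound floor(W/224) * floor(H/224)
  expect_equal(nrow(tile_slide(tm, c(500, 470), 224, 1e-9)$coords), 2 * 2)

  # tile with exactly half its footprint covered: kept at 0.4, dropped at 0.6
  tm$mask[, 1:28] <- FALSE  # left half of the first tile column
  ts_04 <- tile_slide(tm, c(448, 448), 224, 0.4)
  ts_06 <- tile_slide(tm, c(448, 448), 224, 0.6)
  expect_true(any(ts_04$coords[, 1] == 0))
  expect_false(any(ts_06$coords[, 1] == 0))
  # and at exactly 0.5 the >= rule keeps it
  expect_true(any(tile_slide(tm, c(448, 448), 224, 0.5)$coords[, 1] == 0))

  # empty mask and oversize tiles give empty tile sets
  tm$mask[] <- FALSE
  expect_equal(nrow(tile_slide(tm, c(448, 448))$coords), 0)
  expect_equal(nrow(tile_slide(tm, c(100, 100))$coords), 0)

  # deterministic / idempotent
  tm$mask[] <- TRUE
  a <- tile_slide(tm, c(448, 448))
  b <- tile_slide(tm, c(448, 448))
  expect_identical(a$coords, b$coords)
})
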