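test_that("slide generator handles the empty case and is seed-deterministic", {
  spec0 <- synth_slide_spec(width = 128, height = 128, tissue_blobs = 0,
                            blur_patches = 0, dark_labels = 0, fat_holes = 0,
                            seed = 4)
  sl0 <- gen_synthetic_slide(spec0)
  expect_equal(sum(sl0$masks$tissue), 0)
  expect_true(all(sl0$image > 0.9))  # all near-white background

  spec <- synth_slide_spec(width = 192, height = 192, seed = 9)
  a <- gen_synthetic_slide(spec)
  b <- gen_synthetic_slide(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$masks, b$masks)
})

test_that("planted rectangular tissue recovers its area in the ground truth", {
  spec <- synth_slide_spec(width = 320, height = 320,
                           tissue_blobs = list(c(60, 60, 200, 200)),
                           blur_patches = 0, dark_labels = 0, fat_holes = 0,
                           seed = 2)
  sl <- gen_synthetic_slide(spec)
  expect_equal(sum(sl$masks$tissue), 200 * 200)
  expect_true(all(which(sl$masks$tissue, arr.ind = TRUE)[, "row"] %in% 61:260))
})

test_that("conflicting planted regions are rejected", {
  spec <- synth_slide_spec(width = 200, height = 200,
                           tissue_blobs = list(c(20, 20, 100, 100)),
                           blur_patches = 0,
                           dark_labels = list(c(60, 60, 40, 40)),
                           fat_holes = 0, seed = 1)
  expect_error(gen_synthetic_slide(spec), "conflicting")
  out_of_bounds <- synth_slide_spec(width = 100, height = 100,
                                    tissue_blobs = list(c(50, 50, 80, 80)),
                                    blur_patches = 0, dark_labels = 0,
                                    fat_holes = 0, seed = 1)
  expect_error(gen_synthetic_slide(out_of_bounds), "bounds")
})

test_that("bag dataset validates its spec", {
  expect_error(synth_bag_spec(d = 3), "at least 4")
  expect_error(synth_bag_spec(signal_tile_frac = 0), "signal_tile_frac")
  expect_error(synth_bag_spec(signal_tile_frac = 1.5), "signal_tile_frac")
  expect_error(synth_bag_spec(n_slides = 10, prevalence = c(0.01, 0.2, 0.2)),
               "expected count")
})

test_that("bag dataset matches prevalence in expectation and is exclusive", {
  spec <- synth_bag_spec(n_slides = 1000L, bag_size_range = c(5L, 10L), d = 8L,
                         prevalence = c(0.01, 0.02, 0.005), seed = 21L)
  ds <- gen_bag_dataset(spec)
  counts <- colSums(ds$manifest[, c("ROS1", "ALK", "NTRK")])
  # multinomial draws around 10 / 20 / 5
  expect_true(abs(counts[1] - 10) <= 10)
  expect_true(abs(counts[2] - 20) <= 14)
  expect_true(abs(counts[3] - 5) <= 7)
  # realized counts fixed by seed
  expect_identical(gen_bag_dataset(spec)$manifest, ds$manifest)
  # mutual exclusivity
  expect_true(all(rowSums(ds$manifest[, c("ROS1", "ALK", "NTRK")]) <= 1))
  # signal directions orthonormal
  expect_equal(unname(crossprod(ds$directions)), diag(4), tolerance = 1e-10)
})

test_that("null effects make labels independent of features (probe AUC ~ 0.5)", {
  aucs <- vapply(1:5, function(s) {
    spec <- synth_bag_spec(n_slides = 200L, bag_size_range = c(8L, 16L), d = 8L,
                           prevalence = c(0.1, 0.15, 0.1), shared_effect = 0,
                           specific_effect = 0, seed = 100 + s)
    ds <- gen_bag_dataset(spec)
    pooled <- t(vapply(ds$bags, function(b) colMeans(b$features), numeric(8)))
    y <- compose_ran_label(ds$manifest)$RAN
    train <- seq_len(120)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, pooled[train, ]), y[train],
                                           family = stats::binomial()))
    p <- cbind(1, pooled[-train, ]) %*% fit$coefficients
    roc_auc(p, y[-train])
  }, 0)
  # Monte-Carlo CI around chance level
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("strong planted signal is linearly recoverable from pooled bags", {
  aucs <- vapply(1:3, function(s) {
    spec <- synth_bag_spec(n_slides = 300L, bag_size_range = c(10L, 20L),
                           d = 8L, prevalence = c(0.1, 0.15, 0.1),
                           shared_effect = 3, specific_effect = 1.5,
                           signal_tile_frac = 0.25, seed = 200 + s)
    ds <- gen_bag_dataset(spec)
    pooled <- t(vapply(ds$bags, function(b) colMeans(b$features), numeric(8)))
    y <- compose_ran_label(ds$manifest)$RAN
    train <- seq_len(180)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, pooled[train, ]), y[train],
                                           family = stats::binomial()))
    p <- cbind(1, pooled[-train, ]) %*% fit$coefficients
    roc_auc(p, y[-train])
  }, 0)
  expect_gt(mean(aucs), 0.9)
})

test_that("specimen thumbnails are balanced, deterministic, and separable by fragment count", {
  th <- gen_specimen_thumbnails(10, seed = 3)
  expect_equal(sum(th$labels == "biopsy"), 5)
  expect_equal(sum(th$labels == "resection"), 5)
  th2 <- gen_specimen_thumbnails(10, seed = 3)
  expect_identical(th$images, th2$images)

  # connected-component count oracle separates the classes perfectly
  counts <- vapply(th$images, function(im) {
    g <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    max(EBImage::bwlabel((g < 0.85) * 1))
  }, 0)
  expect_true(max(counts[th$labels == "resection"]) <
                min(counts[th$labels == "biopsy"]))
})

test_that("bag dataset round-trips through the directory container", {
  ds <- tiny_bag_dataset()
  dir <- withr::local_tempdir()
  sub <- ds
  sub$bags <- ds$bags[1:3]
  sub$manifest <- ds$manifest[1:3, ]
  write_bag_dataset(sub, dir)
  back <- read_bag_dataset(dir)
  expect_equal(back$manifest$slide_id, sub$manifest$slide_id)
  expect_equal(back$bags[[2]]$features, sub$bags[[2]]$features,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$bags[[2]]$coords, sub$bags[[2]]$coords,
               ignore_attr = TRUE)
})
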