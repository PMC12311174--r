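test_that("pretraining tile sampling clamps, counts, and is deterministic", {
  ts <- function(id, n) structure(list(slide_id = id, tile_size = 224L,
                                       magnification = 10,
                                       coords = cbind(x = seq_len(n) * 224,
                                                      y = rep(0, n))),
                                  class = "tile_set")
  sets <- list(a = ts("a", 5), b = ts("b", 30))
  out <- sample_pretraining_tiles(sets, per_slide = 20, seed = 2)
  expect_equal(sum(out$slide_id == "a"), 5)   # clamped to available tiles
  expect_equal(sum(out$slide_id == "b"), 20)
  expect_identical(out, sample_pretraining_tiles(sets, per_slide = 20, seed = 2))
  expect_warning(sample_pretraining_tiles(list(e = ts("e", 0)), seed = 1),
                 "no tiles")

  many <- stats::setNames(lapply(1:50, function(i) ts(paste0("s", i), 25)),
                          paste0("s", 1:50))
  expect_equal(nrow(sample_pretraining_tiles(many, per_slide = 20, seed = 1)),
               1000)
})

test_that("augmentation pairs are identity at zero strength and seeded", {
  tile <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3))
  id_pair <- augment_pair(tile, seed = 5, crop_min = 1, flip = FALSE, jitter = 0)
  expect_identical(id_pair$view1, tile)
  expect_identical(id_pair$view2, tile)

  p1 <- augment_pair(tile, seed = 7)
  p2 <- augment_pair(tile, seed = 7)
  expect_identical(p1, p2)
  # nonzero strengths perturb the views
  expect_gt(sum((p1$view1 - p1$view2)^2), 0)
  expect_equal(dim(p1$view1), dim(tile))
})

test_that("momentum update follows the convex recursion exactly", {
  key <- list(W = matrix(1, 2, 2), b = c(1, 1))
  query <- list(W = matrix(0, 2, 2), b = c(0, 0))
  expect_identical(momentum_update(key, query, 1), key)
  expect_equal(momentum_update(key, query, 0), query)
  expect_equal(momentum_update(key, query, 0.99)$W[1, 1], 0.99)

  # k momentum updates against a known query trajectory match the closed
  # form m^k * key0 + (1 - m) * sum m^(k-j) q_j
  m <- 0.8
  qs <- lapply(1:4, function(j) list(W = matrix(j, 2, 2), b = rep(j, 2)))
  k <- key
  for (q in qs) k <- momentum_update(k, q, m)
  expected <- m^4 * 1 + (1 - m) * sum(m^(4 - 1:4) * 1:4)
  expect_equal(k$W[1, 1], expected)

  expect_error(momentum_update(list(W = matrix(0, 2, 3)), query["W"], 0.5),
               "shape mismatch")
})

test_that("contrastive loss matches hand-computed values and symmetries", {
  q <- rbind(c(1, 0), c(0, 1))
  expect_equal(contrastive_loss(q, q, tau = 1), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-10)

  # fully degenerate case: loss = log B
  B <- 6
  ones <- matrix(rep(c(1, 0, 0), each = B), B, 3)
  expect_equal(contrastive_loss(ones, ones, tau = 0.5), log(B))

  # invariance under a simultaneous orthogonal rotation
  with_seed_test(3, {
    Q <- matrix(stats::rnorm(12), 4, 3)
    K <- matrix(stats::rnorm(12), 4, 3)
    Q <- Q / sqrt(rowSums(Q^2)); K <- K / sqrt(rowSums(K^2))
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    expect_equal(contrastive_loss(Q, K, 0.2),
                 contrastive_loss(Q %*% R, K %*% R, 0.2), tolerance = 1e-12)
  })
  expect_error(contrastive_loss(q, q, tau = 0), "temperature")
  expect_gte(contrastive_loss(q, q, tau = 0.2), 0)
})

test_that("zero learning rate freezes the query; m = 1 freezes the key", {
  enc <- build_encoder(tiny_encoder_config(seed = 3))
  enc$config$momentum <- 1
  tiles <- random_tiles(6, seed = 4)
  out <- pretrain_encoder(enc, tiles, steps = 1, batch = 4, lr = 0, seed = 9)
  expect_equal(out$query, enc$query, tolerance = 1e-12)
  expect_identical(out$key, enc$key)
})

test_that("contrastive pretraining reduces the loss on structured tiles", {
  enc <- build_encoder(tiny_encoder_config(seed = 1))
  tiles <- random_tiles(24, seed = 2)
  trained <- pretrain_encoder(enc, tiles, steps = 40, batch = 6, lr = 2e-3,
                              seed = 3)
  tr <- trained$loss_trace
  expect_length(tr, 40)
  expect_lt(mean(tail(tr, 5)), mean(head(tr, 5)))
})

test_that("feature extraction is deterministic, batch-invariant, and non-mutating", {
  enc <- build_encoder(tiny_encoder_config(seed = 6))
  tiles <- random_tiles(9, seed = 8)
  before <- enc$query
  b1 <- encode_tiles(enc, tiles, slide_id = "s", batch = 1)
  b32 <- encode_tiles(enc, tiles, slide_id = "s", batch = 32)
  expect_equal(b1$features, b32$features, tolerance = 1e-5)
  expect_identical(b1$features, encode_tiles(enc, tiles, slide_id = "s")$features)
  expect_identical(enc$query, before)
  expect_equal(dim(b1$features), c(9, 8))
  expect_equal(nrow(b1$coords), 9)

  empty <- encode_tiles(enc, list(), slide_id = "none")
  expect_equal(dim(empty$features), c(0, 8))
})
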