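test_that("rollout of uniform and identity attention matches hand evaluation", {
  n <- 4
  uni <- matrix(1 / (n + 1), n + 1, n + 1)
  # one layer: CLS row of 0.5 A + 0.5 I gives each tile 0.5 / (n + 1)
  expect_equal(attention_rollout(list(uni)), rep(0.5 / (n + 1), n))

  eye <- diag(n + 1)
  expect_equal(attention_rollout(list(eye, eye)), rep(0, n))
})

test_that("rollout equals the explicit mixed matrix-product oracle", {
  with_seed_test(13, {
    for (rep in 1:20) {
      n <- sample(2:16, 1)
      L <- sample(1:4, 1)
      H <- sample(1:3, 1)
      attn <- lapply(seq_len(L), function(l) {
        a <- array(0, dim = c(H, n + 1, n + 1))
        for (h in seq_len(H)) a[h, , ] <- random_row_stochastic(n + 1)
        a
      })
      expect_equal(attention_rollout(attn), rollout_oracle(attn),
                   tolerance = 1e-6)
    }
  })
})

test_that("rollout validates row-stochasticity and stays in [0, 1]", {
  bad <- matrix(1, 3, 3)
  expect_error(attention_rollout(list(bad)), "sum to 1")
  with_seed_test(3, {
    attn <- list(random_row_stochastic(6), random_row_stochastic(6))
    r <- attention_rollout(attn)
    expect_true(all(r >= 0 & r <= 1))
    # the full CLS row of the rollout product is a probability vector,
    # so the tile mass is at most 1
    expect_lte(sum(r), 1)
  })
})

test_that("combined map annihilates unattended tiles and commutes with permutation", {
  att <- c(0, 0.2, 0.5)
  cls <- c(0.9, 1, 0.4)
  cm <- combined_map(att, cls)
  expect_equal(cm[1], 0)
  expect_equal(combined_map(att, rep(1, 3)), att)
  perm <- c(3, 1, 2)
  expect_equal(combined_map(att[perm], cls[perm]), cm[perm])
  expect_error(combined_map(1:3, 1:2), "lengths")
})

test_that("classification map delegates to singleton tile scoring", {
  fx <- tiny_trained_model()
  bag <- fx$ds$bags[[1]]
  cm <- classification_map(fx$model, bag)
  expect_equal(cm, tile_scores(fx$model, bag))
  expect_length(cm, nrow(bag$features))
  expect_identical(cm, classification_map(fx$model, bag))
})

test_that("heatmap bundles tie attention, classification, and product together", {
  fx <- tiny_trained_model()
  bag <- fx$ds$bags[[1]]
  hb <- heatmap_bundle(fx$model, bag)
  expect_length(hb$attention, nrow(bag$features))
  expect_equal(hb$combined, hb$attention * hb$classification)
  expect_equal(nrow(hb$coords), nrow(bag$features))
})

test_that("trained attention concentrates on planted signal tiles", {
  # sparse, strong signal tiles: the bag cannot be solved by uniform
  # pooling, so a trained model must attend to the signal tiles
  ratios <- unlist(lapply(5:6, function(seed) {
    spec <- synth_bag_spec(n_slides = 150L, bag_size_range = c(10L, 24L),
                           d = 8L, prevalence = c(0.1, 0.15, 0.08),
                           shared_effect = 4, specific_effect = 1,
                           signal_tile_frac = 0.1, seed = seed)
    ds <- gen_bag_dataset(spec)
    man <- compose_ran_label(ds$manifest)
    plan <- make_cv_splits(man, k = 1L, seed = seed)
    cfg <- train_config(target_label = "RAN", epochs = 8L, lr = 2e-3,
                        seed = seed)
    acfg <- aggregator_config(d_in = 8L, d_model = 8L, n_layers = 2L,
                              n_heads = 2L, d_ff = 16L, d_head = 8L,
                              seed = seed)
    m <- train_direct(ds$bags, man, plan$folds[[1]], cfg, acfg)
    y <- stats::setNames(man$RAN, man$slide_id)
    vapply(names(which(y)), function(id) {
      bag <- ds$bags[[id]]
      sig <- attr(bag, "signal_tiles")
      att <- attention_rollout(forward_bag(m, bag)$attention)
      mean(att[sig]) / mean(att[-sig])
    }, 0)
  }))
  expect_gt(mean(ratios), 1)
})

test_that("overlay rendering is pure and colors tile footprints", {
  thumb <- array(0.9, dim = c(64, 64, 3))
  before <- thumb
  coords <- rbind(c(0, 0), c(224, 0))
  out <- render_overlay(c(0, 1), coords, thumb, scale = 8, tile_size = 224)
  expect_identical(thumb, before)          # input untouched
  expect_equal(dim(out), c(64, 64, 3))
  # the hot tile turns yellow-ish (high R+G, low B), the cold one blue-ish
  expect_gt(mean(out[5:20, 34:50, 1]), mean(out[5:20, 2:20, 1]))
  expect_lt(mean(out[5:20, 34:50, 3]), mean(out[5:20, 2:20, 3]))
  # constant scores tint uniformly
  flat <- render_overlay(c(0.4, 0.4), coords, thumb, scale = 8)
  expect_equal(flat[10, 10, ], flat[10, 40, ], tolerance = 1e-12)
  expect_error(render_overlay(1, rbind(c(6400, 0)), thumb, scale = 8), "outside")
})
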