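# Shared fixtures, built once per test run and cached. All are generated
# in code (no stored data) and sized for a single CPU.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_agg_config <- function(seed = 1L) {
  aggregator_config(d_in = 8L, d_model = 8L, n_layers = 2L, n_heads = 2L,
                    d_ff = 16L, d_head = 8L, seed = seed)
}

tiny_bag_dataset <- function() {
  fixture("tiny_bags", function() {
    spec <- synth_bag_spec(n_slides = 150L, bag_size_range = c(8L, 20L),
                           d = 8L, prevalence = c(0.08, 0.12, 0.05),
                           shared_effect = 3, specific_effect = 1.5,
                           signal_tile_frac = 0.3, seed = 11L)
    gen_bag_dataset(spec)
  })
}

# a small trained model on the tiny dataset (used by interpretability and
# scoring tests)
tiny_trained_model <- function() {
  fixture("tiny_model", function() {
    ds <- tiny_bag_dataset()
    man <- compose_ran_label(ds$manifest)
    plan <- make_cv_splits(man, k = 1L, seed = 3L)
    cfg <- train_config(target_label = "RAN", epochs = 4L, lr = 2e-3, seed = 5L)
    list(model = train_direct(ds$bags, man, plan$folds[[1]], cfg,
                              tiny_agg_config(seed = 2L)),
         ds = ds, man = man, fold = plan$folds[[1]])
  })
}

tiny_encoder_config <- function(seed = 1L) {
  encoder_config(img_size = 32L, patch = 16L, d_model = 16L, n_layers = 2L,
                 n_heads = 2L, d_ff = 24L, out_dim = 8L, seed = seed)
}

random_tiles <- function(n, size = 32L, seed = 1L) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    base <- stats::runif(1)
    array(pmin(pmax(base + stats::rnorm(size * size * 3, sd = 0.1), 0), 1),
          dim = c(size, size, 3))
  }))
}

# seed helper usable inside tests without touching the package namespace
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# exhaustive positive-negative pair counting oracle for ROC AUC (ties 1/2)
pair_count_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# brute-force attention rollout oracle: explicit 0.5-mixed matrix product
rollout_oracle <- function(attn) {
  mats <- lapply(attn, function(a) {
    A <- if (length(dim(a)) == 3) apply(a, c(2, 3), mean) else a
    0.5 * A + 0.5 * diag(nrow(A))
  })
  R <- diag(nrow(mats[[1]]))
  for (m in mats) R <- m %*% R
  R[1, -1]
}

random_row_stochastic <- function(n) {
  m <- matrix(stats::rexp(n * n), n, n)
  m / rowSums(m)
}

# label table with given mutually exclusive positive counts (composite-
# label arithmetic fixtures)
marginal_table <- function(n, ros1, alk, ntrk, prefix = "s") {
  lab <- rep("none", n)
  lab[seq_len(ros1)] <- "ROS1"
  lab[ros1 + seq_len(alk)] <- "ALK"
  lab[ros1 + alk + seq_len(ntrk)] <- "NTRK"
  data.frame(slide_id = paste0(prefix, seq_len(n)),
             ROS1 = lab == "ROS1", ALK = lab == "ALK", NTRK = lab == "NTRK",
             stringsAsFactors = FALSE)
}
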