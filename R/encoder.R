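# Self-supervised tile encoder: a small vision transformer trained with a
# momentum-contrast (dual encoder) objective. The query encoder is updated
# by gradient descent on the InfoNCE loss over in-batch negatives; the key
# encoder never receives gradients and tracks the query encoder through
# momentum updates. After pretraining, tiles are embedded through the
# query encoder into d-dimensional feature vectors (default 384) that form
# the per-slide FeatureBags.

#' Vision-transformer encoder configuration
#'
#' @param img_size tile side length in pixels (must be divisible by
#'   \code{patch}).
#' @param patch patch side length (default 16).
#' @param d_model transformer width.
#' @param n_layers encoder layers.
#' @param n_heads attention heads (divides d_model).
#' @param d_ff feed-forward width.
#' @param out_dim output feature dimension (default 384).
#' @param channels image channels (default 3).
#' @param momentum key-encoder momentum m in \[0, 1\] (default 0.99).
#' @param temperature InfoNCE temperature (> 0, default 0.2).
#' @param seed initialization seed.
#' @return \code{encoder_config} list.
#' @export
encoder_config <- function(img_size = 224L, patch = 16L, d_model = 64L,
                           n_layers = 2L, n_heads = 4L, d_ff = 2L * d_model,
                           out_dim = 384L, channels = 3L, momentum = 0.99,
                           temperature = 0.2, seed = 1L) {
  if (img_size %% patch != 0)
    stop_fusionmil("img_size must be divisible by patch size")
  if (d_model %% n_heads != 0)
    stop_fusionmil("d_model must be divisible by n_heads")
  stopifnot(momentum >= 0, momentum <= 1, temperature > 0)
  structure(list(img_size = as.integer(img_size), patch = as.integer(patch),
                 d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 out_dim = as.integer(out_dim), channels = as.integer(channels),
                 momentum = momentum, temperature = temperature,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

init_vit_params <- function(cfg) {
  n_patches <- (cfg$img_size %/% cfg$patch)^2
  patch_dim <- cfg$patch^2 * cfg$channels
  list(embed = init_linear(patch_dim, cfg$d_model),
       cls = matrix(stats::rnorm(cfg$d_model, sd = 0.02), 1, cfg$d_model),
       pos = matrix(stats::rnorm((n_patches + 1) * cfg$d_model, sd = 0.02),
                    n_patches + 1, cfg$d_model),
       trunk = init_trunk(cfg$d_model, cfg$n_layers, cfg$d_ff),
       ln_f = init_layernorm(cfg$d_model),
       head = init_linear(cfg$d_model, cfg$out_dim))
}

#' Build a dual-encoder (query/key) tile encoder
#'
#' Query and key backbones share the architecture; the key starts as a
#' copy of the query and is only ever updated through
#' \code{\link{momentum_update}}.
#'
#' @param config an \code{\link{encoder_config}}.
#' @return \code{encoder_state} with \code{query} and \code{key} parameter
#'   trees.
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  q <- with_seed(config$seed, init_vit_params(config))
  structure(list(config = config, query = q, key = q, loss_trace = NULL),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Dual-encoder ViT: %dpx/%d patches -> %d-d (d_model %d, %d layers x %d heads)\n",
              cfg$img_size, (cfg$img_size %/% cfg$patch)^2, cfg$out_dim,
              cfg$d_model, cfg$n_layers, cfg$n_heads))
  cat(sprintf("  momentum %.3f, temperature %.2f%s\n", cfg$momentum,
              cfg$temperature,
              if (is.null(x$loss_trace)) "" else sprintf(
                ", trained %d steps (loss %.3f -> %.3f)",
                length(x$loss_trace), x$loss_trace[1],
                x$loss_trace[length(x$loss_trace)])))
  invisible(x)
}

# image array [h, w, c] -> patch matrix [n_patches, patch^2 * c]
patchify <- function(img, patch) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ch <- if (length(dim(img)) == 3) dim(img)[3] else 1
  if (ch == 1) img <- array(img, dim = c(h, w, 1))
  np_r <- h %/% patch; np_c <- w %/% patch
  out <- matrix(0, np_r * np_c, patch * patch * ch)
  k <- 0L
  for (pr in seq_len(np_r)) for (pc in seq_len(np_c)) {
    k <- k + 1L
    block <- img[(pr - 1) * patch + seq_len(patch),
                 (pc - 1) * patch + seq_len(patch), , drop = FALSE]
    out[k, ] <- as.numeric(block)
  }
  out
}

vit_forward <- function(params, cfg, img, want_cache = FALSE) {
  P <- patchify(img, cfg$patch)
  E <- linear_fwd(params$embed, P)
  Tok <- rbind(params$cls, E) + params$pos
  tr <- trunk_fwd(params$trunk, Tok, cfg$n_heads)
  lf <- layernorm_fwd(params$ln_f, tr$Y[1, , drop = FALSE])
  feat <- as.numeric(linear_fwd(params$head, lf$Y))
  out <- list(feature = feat)
  if (want_cache) out$cache <- list(P = P, Tok = Tok, tr = tr, lf = lf)
  out
}

vit_backward <- function(params, cfg, cache, dfeat) {
  hb <- linear_bwd(params$head, cache$lf$Y, matrix(dfeat, 1))
  lf <- layernorm_bwd(params$ln_f, cache$lf, hb$dX)
  dY <- matrix(0, nrow(cache$Tok), cfg$d_model)
  dY[1, ] <- lf$dX
  tb <- trunk_bwd(params$trunk, cache$tr$caches, dY)
  dTok <- tb$dX
  eb <- linear_bwd(params$embed, cache$P, dTok[-1, , drop = FALSE])
  list(embed = eb$grads, cls = dTok[1, , drop = FALSE], pos = dTok,
       trunk = tb$grads, ln_f = lf$grads, head = hb$grads)
}

#' Sample pretraining tiles across slides
#'
#' Selects up to \code{per_slide} random tile coordinates from each
#' slide's tile set, without replacement, for the self-supervised
#' pretraining pool.
#'
#' @param tilesets named list of \code{tile_set} objects.
#' @param per_slide tiles per slide (default 20).
#' @param seed integer seed.
#' @return data.frame with slide_id, x, y; slides with empty tile sets are
#'   skipped with a warning.
#' @export
sample_pretraining_tiles <- function(tilesets, per_slide = 20L, seed = 1L) {
  stopifnot(per_slide >= 1)
  with_seed(seed, {
    rows <- lapply(tilesets, function(ts) {
      n <- nrow(ts$coords)
      if (n == 0) {
        warning("slide ", ts$slide_id, " has no tiles; skipped")
        return(NULL)
      }
      take <- sample(n, min(per_slide, n))
      data.frame(slide_id = ts$slide_id, x = ts$coords[take, 1],
                 y = ts$coords[take, 2])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# bilinear resize of an [h, w, c] array via EBImage
resize_img <- function(img, h, w) {
  if (length(dim(img)) == 2)
    return(as.matrix(EBImage::resize(img, w = h, h = w)))
  out <- array(0, dim = c(h, w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- as.matrix(EBImage::resize(img[, , ch], w = h, h = w))
  out
}

#' Generate two augmented views of a tile
#'
#' Random resized crop, random horizontal/vertical flip, and channel-wise
#' color jitter, applied independently to produce the two views of the
#' contrastive pair. With \code{crop_min = 1}, \code{flip = FALSE} and
#' \code{jitter = 0} both views equal the input tile.
#'
#' @param tile \code{h x w x c} array in \[0, 1\].
#' @param seed integer seed (same seed reproduces the same pair).
#' @param crop_min minimum crop area fraction (default 0.6).
#' @param flip allow random flips (default TRUE).
#' @param jitter color jitter strength (default 0.2).
#' @return list with \code{view1} and \code{view2}, same size as the tile.
#' @export
augment_pair <- function(tile, seed = 1L, crop_min = 0.6, flip = TRUE,
                         jitter = 0.2) {
  h <- dim(tile)[1]; w <- dim(tile)[2]
  one_view <- function() {
    v <- tile
    if (crop_min < 1) {
      frac <- sqrt(stats::runif(1, crop_min, 1))
      ch <- max(2L, round(frac * h)); cw <- max(2L, round(frac * w))
      y0 <- sample.int(h - ch + 1L, 1); x0 <- sample.int(w - cw + 1L, 1)
      v <- v[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
      v <- resize_img(v, h, w)
    }
    if (flip) {
      if (stats::runif(1) < 0.5) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
      if (stats::runif(1) < 0.5) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
    }
    if (jitter > 0) {
      for (ch in seq_len(dim(v)[3])) {
        gain <- 1 + stats::runif(1, -jitter, jitter)
        bias <- stats::runif(1, -jitter / 2, jitter / 2)
        v[, , ch] <- pmin(pmax(v[, , ch] * gain + bias, 0), 1)
      }
    }
    v
  }
  with_seed(seed, list(view1 = one_view(), view2 = one_view()))
}

#' Momentum update of the key encoder
#'
#' Each key parameter moves toward its query counterpart:
#' \code{key <- m * key + (1 - m) * query}. With \code{m = 1} the key is
#' unchanged; with \code{m = 0} it becomes a copy of the query.
#'
#' @param key_params,query_params congruent parameter trees.
#' @param m momentum in \[0, 1\].
#' @return updated key parameter tree.
#' @export
momentum_update <- function(key_params, query_params, m) {
  stopifnot(m >= 0, m <= 1)
  ok <- tryCatch({
    tree_map2(function(k, q) {
      if (!identical(dim(k) %||% length(k), dim(q) %||% length(q)))
        stop("shape mismatch")
      m * k + (1 - m) * q
    }, key_params, query_params)
  }, error = function(e) stop_fusionmil("parameter shape mismatch in momentum update"))
  ok
}

#' InfoNCE contrastive loss over in-batch negatives
#'
#' \code{mean_i -log( exp(q_i . k_i / tau) / sum_j exp(q_i . k_j / tau) )}.
#' Rows are expected L2-normalized; each query's positive is the
#' same-index key and every other in-batch key serves as a negative.
#'
#' @param queries,keys \code{B x d} matrices with L2-normalized rows,
#'   \code{B >= 2}.
#' @param tau temperature (> 0).
#' @return scalar non-negative loss.
#' @export
contrastive_loss <- function(queries, keys, tau = 0.2) {
  if (tau <= 0) stop_fusionmil("temperature must be positive")
  B <- nrow(queries)
  stopifnot(B >= 2, all(dim(queries) == dim(keys)))
  logits <- queries %*% t(keys) / tau
  p <- row_softmax(logits)
  mean(-log(pmax(diag(p), 1e-300)))
}

# gradient of contrastive_loss wrt queries (keys carry no gradient, as in
# momentum contrast)
contrastive_grad_q <- function(queries, keys, tau) {
  B <- nrow(queries)
  p <- row_softmax(queries %*% t(keys) / tau)
  (p - diag(B)) %*% keys / (tau * B)
}

l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  list(Y = X / pmax(nrm, 1e-12), nrm = pmax(nrm, 1e-12))
}

#' Pretrain the tile encoder with momentum contrast
#'
#' Runs the dual-encoder contrastive loop: at each step a batch of tiles
#' is augmented into two views; view 1 goes through the query encoder,
#' view 2 through the key encoder (no gradient); the InfoNCE loss over
#' L2-normalized features updates the query by Adam, after which the key
#' receives a momentum update.
#'
#' @param encoder an \code{\link{build_encoder}} state.
#' @param tiles list of tile arrays (each \code{img_size} square, matching
#'   the encoder config).
#' @param steps optimizer steps.
#' @param batch tiles per step (>= 2).
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param augment_args list passed to \code{\link{augment_pair}}.
#' @return updated \code{encoder_state} with \code{loss_trace}.
#' @export
pretrain_encoder <- function(encoder, tiles, steps = 50L, batch = 8L,
                             lr = 1e-3, seed = 1L, augment_args = list()) {
  stopifnot(inherits(encoder, "encoder_state"), batch >= 2)
  if (length(tiles) < 2)
    stop_fusionmil("need at least 2 tiles for in-batch negatives")
  cfg <- encoder$config
  opt <- adam_init(encoder$query, lr = lr)
  losses <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample(length(tiles), min(batch, length(tiles)))
      qn_list <- vector("list", length(idx))
      caches <- vector("list", length(idx))
      keys <- matrix(0, length(idx), cfg$out_dim)
      for (i in seq_along(idx)) {
        pair <- do.call(augment_pair,
                        c(list(tile = tiles[[idx[i]]],
                               seed = stats::runif(1, 1, 2^30)), augment_args))
        fq <- vit_forward(encoder$query, cfg, pair$view1, want_cache = TRUE)
        fk <- vit_forward(encoder$key, cfg, pair$view2)
        qn_list[[i]] <- fq$feature
        caches[[i]] <- fq$cache
        keys[i, ] <- fk$feature
      }
      Q <- do.call(rbind, qn_list)
      qn <- l2_normalize_rows(Q)
      kn <- l2_normalize_rows(keys)
      losses[s] <- contrastive_loss(qn$Y, kn$Y, cfg$temperature)
      dQn <- contrastive_grad_q(qn$Y, kn$Y, cfg$temperature)
      # back through row normalization
      dQ <- (dQn - qn$Y * rowSums(dQn * qn$Y)) / qn$nrm
      gacc <- NULL
      for (i in seq_along(idx)) {
        g <- vit_backward(encoder$query, cfg, caches[[i]], dQ[i, ])
        gacc <- if (is.null(gacc)) g else tree_map2(`+`, gacc, g)
      }
      st <- adam_step(opt, encoder$query, gacc)
      opt <- st$state
      encoder$query <- st$params
      encoder$key <- momentum_update(encoder$key, encoder$query, cfg$momentum)
    }
  })
  encoder$loss_trace <- c(encoder$loss_trace, losses)
  encoder
}

#' Encode tiles into a feature bag
#'
#' Deterministic inference through the query encoder; augmentation is
#' never applied and encoder parameters are not modified. Rows follow the
#' order of \code{tiles}/\code{coords}.
#'
#' @param encoder a (pre)trained \code{encoder_state}.
#' @param tiles list of tile arrays from one slide.
#' @param coords \code{n x 2} tile coordinate matrix (defaults to a grid).
#' @param slide_id id stored in the bag.
#' @param batch tiles per internal batch; has no effect on the values.
#' @return \code{\link{feature_bag}} of shape \code{n_tiles x out_dim}
#'   (0-row bag for no tiles).
#' @export
encode_tiles <- function(encoder, tiles, coords = NULL, slide_id = "slide",
                         batch = 32L) {
  stopifnot(inherits(encoder, "encoder_state"))
  cfg <- encoder$config
  n <- length(tiles)
  feats <- matrix(0, n, cfg$out_dim)
  if (n > 0) {
    starts <- seq(1L, n, by = batch)
    for (s0 in starts) {
      for (i in s0:min(s0 + batch - 1L, n))
        feats[i, ] <- vit_forward(encoder$query, cfg, tiles[[i]])$feature
    }
  }
  coords <- coords %||% grid_coords(n, cfg$img_size)
  feature_bag(slide_id, feats, coords)
}
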