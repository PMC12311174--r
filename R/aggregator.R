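# Transformer MIL aggregator: projects each tile feature vector to the
# model width, prepends a learned CLS token, runs the token set through
# pre-norm transformer encoder layers (no positional encodings -- a bag is
# an unordered set, so the slide logit is permutation invariant), and
# reads the slide logit off the CLS embedding through a one-hidden-layer
# MLP head.

#' Aggregator configuration
#'
#' @param d_in input feature dimension (tile encoder width, default 384).
#' @param d_model transformer width (default 512); must be divisible by
#'   \code{n_heads}.
#' @param n_layers number of transformer encoder layers (default 2).
#' @param n_heads attention heads per layer (default 8).
#' @param d_ff feed-forward hidden width (default \code{2 * d_model}).
#' @param d_head MLP-head hidden width (default \code{d_model}).
#' @param dropout tile-embedding dropout probability during training
#'   (default 0).
#' @param seed integer seed fixing the parameter initialization.
#' @return \code{aggregator_config} list.
#' @export
aggregator_config <- function(d_in = 384L, d_model = 512L, n_layers = 2L,
                              n_heads = 8L, d_ff = 2L * d_model,
                              d_head = d_model, dropout = 0, seed = 1L) {
  if (d_model %% n_heads != 0)
    stop_fusionmil("d_model (", d_model, ") must be divisible by n_heads (", n_heads, ")")
  stopifnot(d_in >= 1, n_layers >= 1, dropout >= 0, dropout < 1)
  structure(list(d_in = as.integer(d_in), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), d_head = as.integer(d_head),
                 dropout = dropout, seed = as.integer(seed)),
            class = "aggregator_config")
}

#' Build a MIL aggregator model
#'
#' @param config an \code{\link{aggregator_config}}.
#' @return \code{mil_model} object holding the config and parameter tree;
#'   initialization is seed-deterministic.
#' @export
build_aggregator <- function(config) {
  stopifnot(inherits(config, "aggregator_config"))
  params <- with_seed(config$seed, list(
    proj = init_linear(config$d_in, config$d_model),
    cls = matrix(stats::rnorm(config$d_model, sd = 0.02), 1, config$d_model),
    trunk = init_trunk(config$d_model, config$n_layers, config$d_ff),
    ln_f = init_layernorm(config$d_model),
    head1 = init_linear(config$d_model, config$d_head),
    head2 = init_linear(config$d_head, 1L)))
  structure(list(config = config, params = params, trace = NULL),
            class = "mil_model")
}

#' Number of parameters of a MIL aggregator
#' @param model a \code{mil_model}.
#' @return integer parameter count.
#' @export
n_params <- function(model) length(tree_flatten(model$params))

# Core forward pass on a raw feature matrix. `drop_mask` (0/1 per tile)
# implements inverted dropout on the projected tile embeddings.
agg_forward <- function(model, X, want_cache = FALSE, drop_mask = NULL) {
  p <- model$params; cfg <- model$config
  H <- linear_fwd(p$proj, X)
  if (!is.null(drop_mask)) H <- H * (drop_mask / (1 - cfg$dropout))
  Tok <- rbind(p$cls, H)
  tr <- trunk_fwd(p$trunk, Tok, cfg$n_heads, mask_first_key = TRUE)
  lf <- layernorm_fwd(p$ln_f, tr$Y[1, , drop = FALSE])
  H1 <- linear_fwd(p$head1, lf$Y)
  G <- gelu(H1)
  logit <- as.numeric(linear_fwd(p$head2, G))
  out <- list(logit = logit, probability = sigmoid(logit), attention = tr$attn)
  if (want_cache)
    out$cache <- list(X = X, H = H, Tok = Tok, tr = tr, lf = lf, H1 = H1,
                      G = G, drop_mask = drop_mask)
  out
}

# Backward pass: gradient of a scalar loss wrt all parameters, given
# d(loss)/d(logit).
agg_backward <- function(model, cache, dlogit) {
  p <- model$params; cfg <- model$config
  h2 <- linear_bwd(p$head2, cache$G, matrix(dlogit, 1, 1))
  dH1 <- h2$dX * gelu_grad(cache$H1)
  h1 <- linear_bwd(p$head1, cache$lf$Y, dH1)
  lf <- layernorm_bwd(p$ln_f, cache$lf, h1$dX)
  dY <- matrix(0, nrow(cache$Tok), cfg$d_model)
  dY[1, ] <- lf$dX
  tb <- trunk_bwd(p$trunk, cache$tr$caches, dY)
  dcls <- tb$dX[1, , drop = FALSE]
  dH <- tb$dX[-1, , drop = FALSE]
  if (!is.null(cache$drop_mask)) dH <- dH * (cache$drop_mask / (1 - cfg$dropout))
  pj <- linear_bwd(p$proj, cache$X, dH)
  list(grads = list(proj = pj$grads, cls = dcls, trunk = tb$grads,
                    ln_f = lf$grads, head1 = h1$grads, head2 = h2$grads))
}

#' Forward pass on one feature bag
#'
#' @param model a \code{mil_model}.
#' @param bag a \code{\link{feature_bag}} (or plain feature matrix) with
#'   feature dimension equal to \code{config$d_in} and at least one tile.
#' @return list with \code{logit}, \code{probability = sigmoid(logit)},
#'   and \code{attention}: one \code{n_heads x (n_tiles+1) x (n_tiles+1)}
#'   row-stochastic array per layer (token 1 is the CLS token).
#' @export
forward_bag <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"))
  X <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (nrow(X) < 1) stop_fusionmil("empty bag: forward pass needs at least one tile")
  if (ncol(X) != model$config$d_in)
    stop_fusionmil("bag feature dimension ", ncol(X), " != configured d_in ",
                   model$config$d_in)
  agg_forward(model, X)
}

#' Per-tile classification scores
#'
#' Scores each tile by running it through the model as a singleton bag,
#' so a tile's score is independent of the other tiles in its slide. Used
#' for tile-level classification maps.
#'
#' @inheritParams forward_bag
#' @return numeric vector of per-tile probabilities (length
#'   \code{n_tiles}; empty bag gives an empty vector).
#' @export
tile_scores <- function(model, bag) {
  X <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (nrow(X) == 0) return(numeric(0))
  vapply(seq_len(nrow(X)), function(i)
    agg_forward(model, X[i, , drop = FALSE])$probability, 0)
}

#' Predict slide probabilities for a set of bags
#'
#' @param object a \code{mil_model}.
#' @param bags list of \code{feature_bag}s (or a single bag).
#' @param ... unused.
#' @return data.frame with \code{slide_id} and \code{probability}.
#' @export
predict.mil_model <- function(object, bags, ...) {
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  data.frame(
    slide_id = vapply(bags, function(b) b$slide_id %||% NA_character_, ""),
    probability = vapply(bags, function(b) forward_bag(object, b)$probability, 0),
    stringsAsFactors = FALSE)
}

#' @export
print.mil_model <- function(x, ...) {
  cfg <- x$config
  cat("Transformer MIL aggregator\n")
  cat(sprintf("  d_in %d -> d_model %d, %d layers x %d heads, %s parameters\n",
              cfg$d_in, cfg$d_model, cfg$n_layers, cfg$n_heads,
              format(n_params(x), big.mark = ",")))
  if (!is.null(x$trace))
    cat(sprintf("  trained: %d evals, best val AUC %.3f at step %d\n",
                length(x$trace$val_auc), max(x$trace$val_auc),
                x$trace$selected_step))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  print(object)
  if (!is.null(object$trace)) {
    cat("  validation AUC trace:",
        paste(sprintf("%.3f", object$trace$val_auc), collapse = " "), "\n")
    cat("  label:", object$trace$label %||% "?",
        " pos_weight:", object$trace$pos_weight %||% NA, "\n")
  }
  invisible(object)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full config and parameter tree.
#' @param model a \code{mil_model} (or encoder/specimen model).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
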