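# Minimal neural-network core shared by the MIL aggregator, the ViT tile
# encoder and the specimen CNN: parameter trees (nested lists of numeric
# arrays), manual forward/backward passes for linear, layer-norm and
# multi-head self-attention layers, pre-norm transformer blocks, and an
# Adam optimizer over parameter trees. Conventions: activations are
# T x d matrices (rows = tokens), weights are d_in x d_out.

# ---- parameter-tree utilities ------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros_like <- function(a) tree_map(function(x) { x[] <- 0; x }, a)

tree_sq_norm <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sq_norm, 0)) else sum(a^2)
}

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE) else as.numeric(a)
}

tree_unflatten <- function(template, values) {
  pos <- 0L
  rebuild <- function(a) {
    if (is.list(a)) return(lapply(a, rebuild))
    n <- length(a)
    out <- a
    out[] <- values[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  out <- rebuild(template)
  stopifnot(pos == length(values))
  out
}

# ---- initializers -------------------------------------------------------

init_linear <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / (d_in + d_out))), d_in, d_out),
       b = numeric(d_out))
}

init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

# ---- primitive layers ---------------------------------------------------

linear_fwd <- function(p, X) sweep(X %*% p$W, 2, p$b, `+`)

linear_bwd <- function(p, X, dY) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# y = g * (x - mu) / sqrt(var + eps) + b, per row; population variance.
LN_EPS <- 1e-5

layernorm_fwd <- function(p, X) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  Y <- sweep(sweep(xhat, 2, p$g, `*`), 2, p$b, `+`)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(p, cache, dY) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, p$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dX = dX,
       grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

# ---- multi-head self-attention ------------------------------------------

init_mha <- function(d_model) {
  list(q = init_linear(d_model, d_model), k = init_linear(d_model, d_model),
       v = init_linear(d_model, d_model), o = init_linear(d_model, d_model))
}

# `mask_first_key = TRUE` removes token 1 (a CLS readout token) from the
# key/value set: no token attends to it, so its column of every attention
# matrix is zero. This makes the bag model an exact set function --
# duplicating or permuting tiles leaves the CLS output unchanged.
mha_fwd <- function(p, X, n_heads, mask_first_key = FALSE) {
  Tn <- nrow(X); d <- ncol(X); dk <- d %/% n_heads
  Q <- linear_fwd(p$q, X); K <- linear_fwd(p$k, X); V <- linear_fwd(p$v, X)
  O <- matrix(0, Tn, d)
  A <- array(0, dim = c(n_heads, Tn, Tn))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    if (mask_first_key && Tn > 1) S[, 1] <- -1e30
    Ah <- row_softmax(S)
    A[h, , ] <- Ah
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
  }
  Y <- linear_fwd(p$o, O)
  list(Y = Y, cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A,
                           n_heads = n_heads, dk = dk))
}

mha_bwd <- function(p, cache, dY) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  n_heads <- cache$n_heads; dk <- cache$dk
  ob <- linear_bwd(p$o, cache$O, dY)
  dO <- ob$dX
  dQ <- matrix(0, nrow(X), ncol(X)); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    Ah <- cache$A[h, , , drop = TRUE]
    if (is.null(dim(Ah))) Ah <- matrix(Ah, nrow(X), nrow(X))
    dOh <- dO[, idx, drop = FALSE]
    Vh <- V[, idx, drop = FALSE]
    dAh <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    # softmax backward (row-wise)
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, idx] <- dS %*% K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  qb <- linear_bwd(p$q, X, dQ)
  kb <- linear_bwd(p$k, X, dK)
  vb <- linear_bwd(p$v, X, dV)
  list(dX = qb$dX + kb$dX + vb$dX,
       grads = list(q = qb$grads, k = kb$grads, v = vb$grads, o = ob$grads))
}

# ---- pre-norm transformer encoder block ---------------------------------
#   X + MHA(LN1(X)); then + FFN(LN2(.)), FFN = W2 gelu(W1 h + b1) + b2

init_block <- function(d_model, d_ff) {
  list(ln1 = init_layernorm(d_model), attn = init_mha(d_model),
       ln2 = init_layernorm(d_model), ff1 = init_linear(d_model, d_ff),
       ff2 = init_linear(d_ff, d_model))
}

block_fwd <- function(p, X, n_heads, mask_first_key = FALSE) {
  l1 <- layernorm_fwd(p$ln1, X)
  at <- mha_fwd(p$attn, l1$Y, n_heads, mask_first_key)
  X2 <- X + at$Y
  l2 <- layernorm_fwd(p$ln2, X2)
  H1 <- linear_fwd(p$ff1, l2$Y)
  G <- gelu(H1)
  F2 <- linear_fwd(p$ff2, G)
  Y <- X2 + F2
  list(Y = Y, attn = at$cache$A,
       cache = list(l1 = l1, at = at$cache, X2 = X2, l2 = l2, H1 = H1, G = G))
}

block_bwd <- function(p, cache, dY) {
  f2 <- linear_bwd(p$ff2, cache$G, dY)
  dH1 <- f2$dX * gelu_grad(cache$H1)
  f1 <- linear_bwd(p$ff1, cache$l2$Y, dH1)
  l2 <- layernorm_bwd(p$ln2, cache$l2, f1$dX)
  dX2 <- dY + l2$dX
  at <- mha_bwd(p$attn, cache$at, dX2)
  l1 <- layernorm_bwd(p$ln1, cache$l1, at$dX)
  list(dX = dX2 + l1$dX,
       grads = list(ln1 = l1$grads, attn = at$grads, ln2 = l2$grads,
                    ff1 = f1$grads, ff2 = f2$grads))
}

# ---- transformer trunk (stack of blocks) --------------------------------

init_trunk <- function(d_model, n_layers, d_ff) {
  lapply(seq_len(n_layers), function(i) init_block(d_model, d_ff))
}

trunk_fwd <- function(blocks, X, n_heads, mask_first_key = FALSE) {
  caches <- vector("list", length(blocks))
  attn <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    out <- block_fwd(blocks[[i]], X, n_heads, mask_first_key)
    X <- out$Y
    caches[[i]] <- out$cache
    attn[[i]] <- out$attn
  }
  list(Y = X, attn = attn, caches = caches)
}

trunk_bwd <- function(blocks, caches, dY) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    bb <- block_bwd(blocks[[i]], caches[[i]], dY)
    dY <- bb$dX
    grads[[i]] <- bb$grads
  }
  list(dX = dY, grads = grads)
}

# ---- Adam over parameter trees ------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

# Decoupled (AdamW-style) weight decay: applied directly to the
# parameters, not through the gradient moments.
adam_step <- function(state, params, grads, lr = NULL) {
  lr <- lr %||% state$lr
  if (state$weight_decay > 0)
    params <- tree_map(function(p) p * (1 - lr * state$weight_decay), params)
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + state$eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(state = state, params = params)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
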