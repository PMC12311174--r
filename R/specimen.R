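# Thumbnail-level biopsy-vs-resection classifier. The distinction rests
# on coarse morphology -- many small scattered fragments versus one large
# contiguous region -- so a small convolutional network on slide
# thumbnails suffices at desk scale; a deeper VGG-style stack is
# available through the same config for full-size use.

#' Specimen-classifier configuration
#'
#' @param input_size square input side length (default 224; thumbnails
#'   are resized to this).
#' @param backbone "tiny" (two conv layers; desk scale) or "vgg" (deeper
#'   VGG-style stack).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 25).
#' @param augment apply random flips/rotations/color jitter during
#'   training (default TRUE); never applied at inference.
#' @param seed integer seed.
#' @return \code{specimen_config} list.
#' @export
specimen_config <- function(input_size = 224L, backbone = c("tiny", "vgg"),
                            lr = 0.001, batch_size = 32L, epochs = 25L,
                            augment = TRUE, seed = 1L) {
  backbone <- match.arg(backbone)
  structure(list(input_size = as.integer(input_size), backbone = backbone,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 seed = as.integer(seed)),
            class = "specimen_config")
}

# conv layer shapes per backbone: list of (filters, kernel, stride)
backbone_spec <- function(backbone) {
  if (backbone == "tiny")
    list(c(8L, 5L, 2L), c(16L, 3L, 2L))
  else
    list(c(16L, 3L, 1L), c(16L, 3L, 2L), c(32L, 3L, 1L), c(32L, 3L, 2L),
         c(64L, 3L, 2L))
}

# precompute im2col index matrix for H x W x C input, kernel k, stride s
im2col_idx <- function(H, W, C, k, s) {
  oh <- (H - k) %/% s + 1L
  ow <- (W - k) %/% s + 1L
  base_r <- rep(seq(0L, (oh - 1L) * s, by = s), times = ow)
  base_c <- rep(seq(0L, (ow - 1L) * s, by = s), each = oh)
  off <- expand.grid(dr = seq_len(k), dc = seq_len(k), ch = seq_len(C))
  idx <- matrix(0L, oh * ow, k * k * C)
  for (j in seq_len(nrow(off)))
    idx[, j] <- (off$ch[j] - 1L) * H * W + (base_c + off$dc[j] - 1L) * H +
      base_r + off$dr[j]
  list(idx = idx, oh = oh, ow = ow)
}

conv_fwd <- function(p, x, ii) {
  col <- matrix(x[ii$idx], nrow(ii$idx), ncol(ii$idx))
  z <- sweep(col %*% p$W, 2, p$b, `+`)
  a <- pmax(z, 0)
  list(a = array(a, dim = c(ii$oh, ii$ow, ncol(p$W))), col = col, z = z)
}

conv_bwd <- function(p, cache, ii, dA, in_dim) {
  dZ <- matrix(dA, nrow(cache$z), ncol(cache$z)) * (cache$z > 0)
  dW <- crossprod(cache$col, dZ)
  db <- colSums(dZ)
  dcol <- dZ %*% t(p$W)
  dx <- numeric(prod(in_dim))
  for (j in seq_len(ncol(ii$idx)))
    dx[ii$idx[, j]] <- dx[ii$idx[, j]] + dcol[, j]
  list(dx = array(dx, dim = in_dim), grads = list(W = dW, b = db))
}

init_specimen_params <- function(cfg) {
  layers <- backbone_spec(cfg$backbone)
  size <- cfg$input_size; C <- 3L
  convs <- list(); iis <- list()
  for (i in seq_along(layers)) {
    f <- layers[[i]][1]; k <- layers[[i]][2]; s <- layers[[i]][3]
    fan_in <- k * k * C
    convs[[i]] <- list(W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)),
                                  fan_in, f),
                       b = numeric(f))
    ii <- im2col_idx(size, size, C, k, s)
    iis[[i]] <- c(ii, list(in_dim = c(size, size, C)))
    size <- ii$oh; C <- f
  }
  list(params = list(convs = convs, dense = init_linear(C, 2L)), iis = iis)
}

specimen_forward <- function(model, img, want_cache = FALSE) {
  x <- img
  caches <- list()
  for (i in seq_along(model$params$convs)) {
    out <- conv_fwd(model$params$convs[[i]], x, model$iis[[i]])
    caches[[i]] <- out
    x <- out$a
  }
  gap <- apply(x, 3, mean)
  logits <- as.numeric(linear_fwd(model$params$dense, matrix(gap, 1)))
  p <- exp(logits - max(logits)); p <- p / sum(p)
  out <- list(prob = p, logits = logits)
  if (want_cache) out$cache <- list(convs = caches, gap = gap,
                                    map_dim = dim(x))
  out
}

specimen_backward <- function(model, cache, dlogits) {
  db <- linear_bwd(model$params$dense, matrix(cache$gap, 1),
                   matrix(dlogits, 1))
  md <- cache$map_dim
  dgap <- as.numeric(db$dX)
  dA <- array(rep(dgap, each = md[1] * md[2]) / (md[1] * md[2]), dim = md)
  grads_convs <- vector("list", length(model$params$convs))
  for (i in rev(seq_along(model$params$convs))) {
    cb <- conv_bwd(model$params$convs[[i]], cache$convs[[i]], model$iis[[i]],
                   dA, model$iis[[i]]$in_dim)
    grads_convs[[i]] <- cb$grads
    dA <- cb$dx
  }
  list(convs = grads_convs, dense = db$grads)
}

augment_thumbnail <- function(img) {
  if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (stats::runif(1) < 0.5) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  rot <- sample(0:3, 1)
  if (rot > 0) for (r in seq_len(rot)) img <- aperm(img, c(2, 1, 3))[, rev(seq_len(dim(img)[1])), , drop = FALSE]
  # mild gain jitter: strong luminance jitter would corrupt the
  # tissue-area signal the task rests on
  gain <- 1 + stats::runif(1, -0.03, 0.03)
  pmin(pmax(img * gain, 0), 1)
}

prep_thumb <- function(img, size, warn_resize = FALSE) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (!all(dim(img)[1:2] == size)) {
    if (warn_resize) warning("thumbnail resized to ", size, "x", size)
    img <- resize_img(img, size, size)
  }
  img
}

#' Train the biopsy-vs-resection thumbnail classifier
#'
#' Cross-entropy training with Adam; thumbnails are resized to
#' \code{input_size} and randomly flipped/rotated/jittered during
#' training when \code{augment} is on. Training is seed-deterministic.
#'
#' @param thumbnails list of thumbnail arrays.
#' @param labels character vector ("biopsy"/"resection"), both classes
#'   present.
#' @param config a \code{\link{specimen_config}}.
#' @return \code{specimen_model} with a per-epoch training-accuracy
#'   \code{trace}.
#' @export
train_specimen_classifier <- function(thumbnails, labels,
                                      config = specimen_config()) {
  stopifnot(inherits(config, "specimen_config"),
            length(thumbnails) == length(labels))
  classes <- c("biopsy", "resection")
  y <- match(labels, classes)
  if (anyNA(y) || length(unique(y)) < 2)
    stop_fusionmil("labels must contain both 'biopsy' and 'resection'")
  built <- with_seed(config$seed, init_specimen_params(config))
  model <- structure(list(params = built$params, iis = built$iis,
                          config = config, classes = classes, trace = NULL),
                     class = "specimen_model")
  imgs <- lapply(thumbnails, prep_thumb, size = config$input_size)
  opt <- adam_init(model$params, lr = config$lr)
  acc_trace <- numeric(config$epochs)
  with_seed(child_seed(config$seed, 3L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(imgs))
      correct <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        gacc <- NULL
        for (i in bidx) {
          im <- if (config$augment) augment_thumbnail(imgs[[i]]) else imgs[[i]]
          fw <- specimen_forward(model, im, want_cache = TRUE)
          if (which.max(fw$prob) == y[i]) correct <- correct + 1L
          dlog <- fw$prob
          dlog[y[i]] <- dlog[y[i]] - 1
          g <- specimen_backward(model, fw$cache, dlog / length(bidx))
          gacc <- if (is.null(gacc)) g else tree_map2(`+`, gacc, g)
        }
        st <- adam_step(opt, model$params, gacc)
        opt <- st$state
        model$params <- st$params
      }
      acc_trace[epoch] <- correct / length(ord)
    }
  })
  model$trace <- acc_trace
  model
}

#' Predict specimen type for a thumbnail
#'
#' Deterministic inference (no augmentation); thumbnails of the wrong
#' size are resized with a warning.
#'
#' @param model a trained \code{specimen_model}.
#' @param thumbnail image array.
#' @return list with \code{label} ("biopsy"/"resection") and
#'   \code{probability} (softmax vector over both classes, summing to 1).
#' @export
predict_specimen <- function(model, thumbnail) {
  stopifnot(inherits(model, "specimen_model"))
  img <- prep_thumb(thumbnail, model$config$input_size, warn_resize = TRUE)
  fw <- specimen_forward(model, img)
  list(label = model$classes[which.max(fw$prob)],
       probability = stats::setNames(fw$prob, model$classes))
}

#' @export
print.specimen_model <- function(x, ...) {
  cat("Specimen-type classifier (", x$config$backbone, "backbone,",
      x$config$input_size, "px input)\n")
  if (!is.null(x$trace))
    cat(sprintf("  trained %d epochs, final train accuracy %.3f\n",
                length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}
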