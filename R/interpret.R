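# Attention-rollout interpretability. The aggregator's attention matrices
# are head-averaged per layer, mixed half-and-half with the identity to
# account for the residual path, and multiplied across layers; the CLS row
# of the product attributes the slide prediction to individual tiles.
# Combined with per-tile classification scores this yields the
# attention-by-classification maps: a tile matters when it both looks
# fusion-positive and is attended to.

#' Attention rollout across transformer layers
#'
#' For each layer, heads are averaged into \code{A}, residual-mixed as
#' \code{0.5 A + 0.5 I}, and the mixed matrices are multiplied from the
#' last layer down to the first. The result's CLS row over tile columns is
#' the per-tile attention vector. Attention mass on the CLS token itself
#' is excluded but the vector is not re-scaled; min-max scaling is a
#' rendering concern (\code{\link{render_overlay}}).
#'
#' @param attn list (one element per layer, first layer first) of
#'   \code{n_heads x (n+1) x (n+1)} arrays (or \code{(n+1) x (n+1)}
#'   matrices) of row-stochastic attention; token 1 is CLS.
#' @return numeric vector of per-tile attention (length n).
#' @export
attention_rollout <- function(attn) {
  stopifnot(length(attn) >= 1)
  mixed <- lapply(attn, function(a) {
    A <- if (length(dim(a)) == 3) apply(a, c(2, 3), mean) else as.matrix(a)
    if (any(abs(rowSums(A) - 1) > 1e-3))
      stop_fusionmil("attention rows must sum to 1")
    0.5 * A + 0.5 * diag(nrow(A))
  })
  R <- Reduce(`%*%`, rev(mixed))
  as.numeric(R[1, -1])
}

#' Per-tile classification map
#'
#' Delegates to \code{\link{tile_scores}}: each tile's feature vector is
#' passed independently (as a singleton bag) through the trained
#' classifier.
#'
#' @inheritParams forward_bag
#' @return numeric vector of per-tile probabilities.
#' @export
classification_map <- function(model, bag) tile_scores(model, bag)

#' Attention-by-classification map
#'
#' Element-wise product of attention and classification scores. Tiles
#' with high classification scores but negligible attention contribute
#' nothing, mirroring how little such regions influence the slide
#' prediction.
#'
#' @param attention,classification equal-length numeric vectors.
#' @return element-wise product vector.
#' @export
combined_map <- function(attention, classification) {
  if (length(attention) != length(classification))
    stop_fusionmil("attention and classification lengths differ")
  attention * classification
}

#' Compute the full heatmap bundle for one slide
#'
#' @inheritParams forward_bag
#' @return \code{heatmap_bundle}: \code{attention} (rollout),
#'   \code{classification}, \code{combined}, and the bag's \code{coords}.
#' @export
heatmap_bundle <- function(model, bag) {
  fw <- forward_bag(model, bag)
  att <- attention_rollout(fw$attention)
  cls <- tile_scores(model, bag)
  structure(list(attention = att, classification = cls,
                 combined = combined_map(att, cls),
                 coords = bag$coords, slide_id = bag$slide_id,
                 probability = fw$probability),
            class = "heatmap_bundle")
}

#' @export
print.heatmap_bundle <- function(x, ...) {
  cat("HeatmapBundle", x$slide_id, ":", length(x$attention), "tiles,",
      sprintf("slide probability %.3f\n", x$probability))
  invisible(x)
}

# blue->yellow (attention) and white->red (classification) color ramps
ramp_color <- function(v, palette = c("attention", "classification")) {
  palette <- match.arg(palette)
  v <- pmin(pmax(v, 0), 1)
  if (palette == "attention") {
    cbind(r = v, g = v, b = 1 - v)
  } else {
    cbind(r = rep(1, length(v)), g = 1 - v, b = 1 - v)
  }
}

#' Render a per-tile score overlay onto a thumbnail
#'
#' Colors each tile footprint (mapped into the thumbnail frame through
#' \code{scale}) by its min-max-scaled score -- blue-to-yellow for
#' attention maps, white-to-red for classification maps -- alpha-blended
#' over the thumbnail, with a color-bar legend strip along the bottom
#' edge. The input image is not modified.
#'
#' @param scores per-tile numeric scores.
#' @param coords \code{n x 2} tile (x, y) at working resolution.
#' @param thumbnail \code{h x w (x 3)} array.
#' @param scale working-resolution to thumbnail downsample factor.
#' @param tile_size tile side at working resolution (default 224).
#' @param colormap "attention" or "classification".
#' @param alpha overlay opacity (default 0.6).
#' @return new \code{h x w x 3} array.
#' @export
render_overlay <- function(scores, coords, thumbnail, scale = 1,
                           tile_size = 224L,
                           colormap = c("attention", "classification"),
                           alpha = 0.6) {
  colormap <- match.arg(colormap)
  stopifnot(length(scores) == nrow(coords))
  g <- thumbnail
  if (length(dim(g)) == 2) g <- array(rep(g, 3), dim = c(dim(g), 3))
  out <- g
  h <- dim(out)[1]; w <- dim(out)[2]
  rngv <- range(scores)
  sc <- if (diff(rngv) > 0) (scores - rngv[1]) / diff(rngv) else rep(0.5, length(scores))
  cols <- ramp_color(sc, colormap)
  for (i in seq_len(nrow(coords))) {
    x0 <- floor(coords[i, 1] / scale) + 1L
    y0 <- floor(coords[i, 2] / scale) + 1L
    x1 <- min(w, ceiling((coords[i, 1] + tile_size) / scale))
    y1 <- min(h, ceiling((coords[i, 2] + tile_size) / scale))
    if (x0 > w || y0 > h || x0 < 1 || y0 < 1)
      stop_fusionmil("tile coordinates map outside the thumbnail")
    for (ch in 1:3)
      out[y0:y1, x0:x1, ch] <-
        (1 - alpha) * out[y0:y1, x0:x1, ch] + alpha * cols[i, ch]
  }
  # legend: color-bar strip along the bottom edge
  leg_h <- max(2L, round(h * 0.03))
  ramp <- ramp_color(seq(0, 1, length.out = w), colormap)
  for (ch in 1:3)
    out[(h - leg_h + 1):h, , ch] <- matrix(ramp[, ch], leg_h, w, byrow = TRUE)
  out
}
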