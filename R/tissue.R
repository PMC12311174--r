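# Sequential tissue masking and tiling. Each filter stage refines one
# shared binary keep-mask computed at thumbnail resolution: sharpness
# (Laplacian-of-Gaussian magnitude), texture (local deviation), then
# morphological cleanup, then intensity/shape heuristics for fat-like
# holes and dark label artifacts. Grid-aligned non-overlapping tiles are
# then read off the mask at working resolution.
#
# All images are [h, w(, 3)] arrays in [0, 1]. Masks are logical [h, w]
# matrices at thumbnail scale. The filters use symmetric kernels, so
# passing row-major matrices through EBImage's x/y-indexed routines is
# orientation-safe.

to_gray <- function(img) {
  if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
}

#' Extract a low-resolution thumbnail
#'
#' @param slide_image \code{h x w (x 3)} array in \[0, 1\].
#' @param target_downsample downsample factor (>= 1); output dimensions
#'   are \code{ceiling(dim / target_downsample)}, preserving aspect ratio.
#' @return thumbnail array with a \code{"downsample"} attribute recording
#'   the factor.
#' @export
extract_thumbnail <- function(slide_image, target_downsample = 32) {
  d <- dim(slide_image)
  if (is.null(d) || length(slide_image) == 0 || any(d[1:2] == 0))
    stop_fusionmil("unreadable or empty slide image")
  stopifnot(target_downsample >= 1)
  out_h <- ceiling(d[1] / target_downsample)
  out_w <- ceiling(d[2] / target_downsample)
  if (target_downsample == 1) {
    out <- slide_image
  } else if (length(d) == 3) {
    out <- array(0, dim = c(out_h, out_w, d[3]))
    for (ch in seq_len(d[3]))
      out[, , ch] <- as.matrix(EBImage::resize(slide_image[, , ch],
                                               w = out_h, h = out_w))
  } else {
    out <- as.matrix(EBImage::resize(slide_image, w = out_h, h = out_w))
  }
  attr(out, "downsample") <- target_downsample
  out
}

#' Sharpness keep-mask (blur filter)
#'
#' Keeps pixels whose Gaussian-smoothed Laplacian magnitude reaches
#' \code{threshold}: textured tissue has strong local second derivatives,
#' while out-of-focus patches and flat background do not.
#'
#' @param thumbnail image array; converted to grayscale internally.
#' @param sigma Gaussian smoothing bandwidth in pixels (> 0, default 2).
#' @param threshold keep threshold on the smoothed Laplacian magnitude.
#' @return logical keep-mask.
#' @export
blur_mask <- function(thumbnail, sigma = 2, threshold = 0.02) {
  stopifnot(sigma > 0)
  g <- to_gray(thumbnail)
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- abs(as.matrix(EBImage::filter2(g, lap_kernel)))
  sm <- as.matrix(EBImage::gblur(lap, sigma = sigma))
  sm >= threshold
}

#' Texture keep-mask (flat-region filter)
#'
#' Drops pixels whose local root-mean-square deviation from the window
#' mean falls below \code{flat_tol} -- uniform-intensity background and
#' other featureless regions.
#'
#' @param thumbnail image array.
#' @param window odd box-window side length (>= 3).
#' @param flat_tol minimum local deviation to keep a pixel.
#' @return logical keep-mask.
#' @export
flat_mask <- function(thumbnail, window = 5L, flat_tol = 0.02) {
  stopifnot(window >= 3, window %% 2 == 1)
  g <- to_gray(thumbnail)
  box <- matrix(1 / window^2, window, window)
  mu <- as.matrix(EBImage::filter2(g, box))
  ex2 <- as.matrix(EBImage::filter2(g^2, box))
  local_sd <- sqrt(pmax(ex2 - mu^2, 0))
  local_sd >= flat_tol
}

label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  list(lab = as.matrix(lab), n = max(lab))
}

#' Morphological mask refinement
#'
#' Removes connected foreground components smaller than \code{min_object}
#' pixels (components of exactly \code{min_object} pixels are kept) and
#' fills enclosed background holes smaller than \code{max_hole} pixels.
#'
#' @param mask logical matrix.
#' @param min_object minimum component size to keep, in pixels.
#' @param max_hole holes strictly smaller than this are filled.
#' @return logical mask.
#' @export
refine_mask <- function(mask, min_object = 8L, max_hole = 16L) {
  mask <- mask == 1
  if (min_object > 1 && any(mask)) {
    cc <- label_components(mask)
    sizes <- tabulate(cc$lab[cc$lab > 0], nbins = cc$n)
    drop <- which(sizes < min_object)
    if (length(drop)) mask[cc$lab %in% drop] <- FALSE
  }
  if (max_hole > 0 && any(!mask)) {
    bg <- label_components(!mask)
    if (bg$n > 0) {
      sizes <- tabulate(bg$lab[bg$lab > 0], nbins = bg$n)
      border_labs <- unique(c(bg$lab[1, ], bg$lab[nrow(mask), ],
                              bg$lab[, 1], bg$lab[, ncol(mask)]))
      fill <- setdiff(which(sizes < max_hole), border_labs)
      if (length(fill)) mask[bg$lab %in% fill] <- TRUE
    }
  }
  mask
}

#' Remove fat-like holes and dark label artifacts
#'
#' Two intensity/shape heuristics that only ever remove mask pixels:
#' (1) connected near-white regions (mean intensity above
#' \code{density_tol}) that are enclosed in the image interior -- fat-like
#' low-density areas, including holes re-filled by
#' \code{\link{refine_mask}} -- are removed with a one-pixel margin;
#' (2) connected near-black regions (mean intensity below \code{dark_tol})
#' whose rectangularity (area / bounding-box area) exceeds
#' \code{shape_params$rect_min} -- printed slide labels and similar dark
#' rectangles -- are removed with a two-pixel margin, which also clears
#' the high-gradient halo the sharpness filter keeps around them.
#'
#' @param mask logical matrix.
#' @param thumbnail image array of the same spatial size.
#' @param density_tol near-white mean-intensity threshold (default 0.85).
#' @param dark_tol near-black mean-intensity threshold (default 0.25).
#' @param shape_params list with \code{rect_min} (default 0.7).
#' @return logical mask.
#' @export
remove_fat_and_dark <- function(mask, thumbnail, density_tol = 0.85,
                                dark_tol = 0.25,
                                shape_params = list(rect_min = 0.7)) {
  g <- to_gray(thumbnail)
  if (!all(dim(mask) == dim(g)))
    stop_fusionmil("mask and thumbnail dimensions differ")
  mask <- mask == 1
  dilate_px <- function(m, px) {
    as.matrix(EBImage::dilate(m * 1, EBImage::makeBrush(2L * px + 1L, "box"))) > 0
  }
  # fat-like: enclosed near-white regions (component mean > density_tol
  # by construction); the image-border background is not enclosed
  bright <- g > density_tol
  if (any(bright)) {
    cc <- label_components(bright)
    if (cc$n > 0) {
      border_labs <- unique(c(cc$lab[1, ], cc$lab[nrow(g), ],
                              cc$lab[, 1], cc$lab[, ncol(g)]))
      fat_labs <- setdiff(seq_len(cc$n), border_labs)
      if (length(fat_labs))
        mask <- mask & !dilate_px(matrix(cc$lab %in% fat_labs, nrow(g)), 1L)
    }
  }
  # dark rectangles: near-black components (mean < dark_tol by
  # construction) with high rectangularity
  dark <- g < dark_tol
  if (any(dark)) {
    cc <- label_components(dark)
    if (cc$n > 0) {
      kill <- matrix(FALSE, nrow(g), ncol(g))
      found <- FALSE
      for (k in seq_len(cc$n)) {
        px <- cc$lab == k
        rows <- range(row(px)[px]); cols <- range(col(px)[px])
        rectangularity <- sum(px) /
          ((rows[2] - rows[1] + 1) * (cols[2] - cols[1] + 1))
        if (rectangularity > shape_params$rect_min) {
          kill <- kill | px
          found <- TRUE
        }
      }
      if (found) mask <- mask & !dilate_px(kill, 2L)
    }
  }
  mask
}

#' Tissue-mask stage configuration
#'
#' The sharpness and texture thresholds default to fixed fractions of the
#' thumbnail's dynamic range, making the chain robust to overall
#' brightness; every stage parameter is exposed here.
#'
#' @param sigma blur-filter Gaussian bandwidth (px).
#' @param blur_frac sharpness threshold as a fraction of dynamic range.
#' @param window flat-filter box window (odd, px).
#' @param flat_frac texture threshold as a fraction of dynamic range.
#' @param min_object,max_hole morphological refinement sizes (px).
#' @param density_tol,dark_tol,rect_min fat/dark heuristics (see
#'   \code{\link{remove_fat_and_dark}}).
#' @param edge_trim final erosion in pixels (default 1); strips the
#'   high-gradient transition halo the sharpness filter keeps along
#'   tissue-background boundaries.
#' @return list of stage parameters.
#' @export
mask_config <- function(sigma = 1.5, blur_frac = 0.09, window = 5L,
                        flat_frac = 0.03, min_object = 8L, max_hole = 16L,
                        density_tol = 0.85, dark_tol = 0.25, rect_min = 0.7,
                        edge_trim = 1L) {
  list(sigma = sigma, blur_frac = blur_frac, window = window,
       flat_frac = flat_frac, min_object = min_object, max_hole = max_hole,
       density_tol = density_tol, dark_tol = dark_tol, rect_min = rect_min,
       edge_trim = as.integer(edge_trim))
}

#' Build the sequential tissue mask
#'
#' Applies the filter chain to a thumbnail -- sharpness AND texture
#' keep-masks, morphological refinement, then fat/dark artifact removal --
#' recording per-stage pixel deltas in \code{stage_log}. All stages except
#' hole-filling only remove pixels.
#'
#' @param thumbnail image array (with a \code{"downsample"} attribute if
#'   produced by \code{\link{extract_thumbnail}}).
#' @param config a \code{\link{mask_config}}.
#' @param scale thumbnail-to-working-resolution factor; defaults to the
#'   thumbnail's \code{"downsample"} attribute (or 1).
#' @return \code{tissue_mask} object: \code{mask} (logical, thumbnail
#'   scale), \code{scale}, and \code{stage_log} (data.frame of stage name
#'   and signed pixel delta).
#' @export
build_tissue_mask <- function(thumbnail, config = mask_config(), scale = NULL) {
  g <- to_gray(thumbnail)
  # dynamic range with a floor: a thumbnail whose total contrast is tiny
  # (blank slide) must not have its sensor noise promoted to "texture"
  rng <- max(diff(range(g)), 0.5)
  scale <- scale %||% attr(thumbnail, "downsample") %||% 1
  log_df <- data.frame(stage = character(), delta_pixels = integer())
  note <- function(stage, before, after) {
    log_df <<- rbind(log_df, data.frame(stage = stage,
                                        delta_pixels = sum(after) - sum(before)))
    after
  }
  all_px <- matrix(TRUE, nrow(g), ncol(g))
  m_blur <- blur_mask(thumbnail, sigma = config$sigma,
                      threshold = config$blur_frac * rng)
  m <- note("blur", all_px, m_blur)
  m <- note("flat", m, m & flat_mask(thumbnail, window = config$window,
                                     flat_tol = config$flat_frac * rng))
  m <- note("remove_small_objects", m,
            refine_mask(m, min_object = config$min_object, max_hole = 0))
  m <- note("fill_holes", m,
            refine_mask(m, min_object = 1, max_hole = config$max_hole))
  m <- note("fat_dark", m,
            remove_fat_and_dark(m, thumbnail, density_tol = config$density_tol,
                                dark_tol = config$dark_tol,
                                shape_params = list(rect_min = config$rect_min)))
  if (config$edge_trim > 0 && any(m))
    m <- note("edge_trim", m, as.matrix(EBImage::erode(
      m * 1, EBImage::makeBrush(2L * config$edge_trim + 1L, "box"))) > 0)
  structure(list(mask = m, scale = scale, stage_log = log_df),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat("TissueMask", paste(dim(x$mask), collapse = "x"), "at 1/", x$scale,
      "scale;", sum(x$mask), "foreground px\n")
  print(x$stage_log)
  invisible(x)
}

#' Extract non-overlapping tile coordinates
#'
#' Emits grid-aligned, non-overlapping \code{tile_size} tiles (at working
#' resolution) whose footprint is covered by the tissue mask for at least
#' \code{coverage_min} of its area. Coverage is computed exactly from the
#' mask geometry, treating each thumbnail pixel as a \code{scale x scale}
#' square with fractional overlap at tile edges. Coordinates are 0-based
#' top-left corners with half-open footprints.
#'
#' @param mask a \code{\link{build_tissue_mask}} result.
#' @param image_dims working-resolution \code{c(height, width)} of the
#'   slide.
#' @param tile_size tile side length in pixels (default 224).
#' @param coverage_min minimum mask-covered fraction in (0, 1\].
#' @param slide_id optional id stored in the tile set.
#' @param magnification stored working magnification label (default 10).
#' @return \code{tile_set}: \code{coords} matrix of (x, y), plus
#'   \code{tile_size}, \code{magnification}, \code{slide_id}. A tile size
#'   exceeding the image yields an empty tile set.
#' @export
tile_slide <- function(mask, image_dims, tile_size = 224L, coverage_min = 0.5,
                       slide_id = NA_character_, magnification = 10) {
  stopifnot(inherits(mask, "tissue_mask"), coverage_min > 0, coverage_min <= 1)
  h <- image_dims[1]; w <- image_dims[2]
  s <- mask$scale
  m <- mask$mask
  xs <- if (w >= tile_size) seq(0L, w - tile_size, by = tile_size) else integer(0)
  ys <- if (h >= tile_size) seq(0L, h - tile_size, by = tile_size) else integer(0)
  # fractional overlap weight of each thumbnail row/col with [a, a+tile)
  overlap_w <- function(a, n_px) {
    lo <- a / s; hi <- (a + tile_size) / s
    j <- seq_len(n_px)
    pmax(0, pmin(j, hi) - pmax(j - 1, lo))
  }
  coords <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  area <- (tile_size / s)^2
  for (y0 in ys) {
    wr <- overlap_w(y0, nrow(m))
    ri <- which(wr > 0)
    for (x0 in xs) {
      wc <- overlap_w(x0, ncol(m))
      ci <- which(wc > 0)
      cov <- as.numeric(wr[ri] %*% m[ri, ci, drop = FALSE] %*% wc[ci]) / area
      if (cov >= coverage_min) coords <- rbind(coords, c(x0, y0))
    }
  }
  structure(list(slide_id = slide_id, tile_size = as.integer(tile_size),
                 magnification = magnification, coords = coords),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat("TileSet", x$slide_id, ":", nrow(x$coords), "tiles of",
      x$tile_size, "px at", x$magnification, "x\n")
  invisible(x)
}

#' Write a tile set to CSV
#'
#' @param tileset a \code{tile_set}.
#' @param path CSV path (columns slide_id, x, y, tile_size).
#' @export
write_tileset <- function(tileset, path) {
  utils::write.csv(data.frame(slide_id = tileset$slide_id,
                              x = tileset$coords[, 1], y = tileset$coords[, 2],
                              tile_size = tileset$tile_size),
                   path, row.names = FALSE)
  invisible(path)
}
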