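# Synthetic slide-image generator. Produces desk-scale raster "slides"
# with the artifact classes the tissue-masking chain must handle: textured
# tissue blobs on a near-white background, Gaussian-blurred patches,
# near-black label rectangles, and enclosed low-density (fat-like) holes
# inside tissue -- each with a binary ground-truth mask. No attempt is made
# at photorealistic histology texture; the generator only reproduces the
# intensity/texture statistics each filter stage keys on.
#
# Images are numeric arrays [height, width, 3] with values in [0, 1].

#' Specification for a synthetic slide image
#'
#' Planted regions may be given as rectangles \code{c(x, y, w, h)}
#' (0-based top-left, half-open) or as an integer count for seeded
#' automatic placement. Automatic placement keeps conflicting classes
#' disjoint; explicitly specified regions are checked and rejected if
#' classes conflict.
#'
#' @param width,height image size in pixels.
#' @param tissue_blobs integer count of irregular tissue blobs, or a list
#'   of rects for exactly-placed rectangular tissue patches.
#' @param blur_patches integer count or list of rects (blurred tissue).
#' @param dark_labels integer count or list of rects (near-black label
#'   artifacts on background).
#' @param fat_holes integer count or list of rects (enclosed near-white
#'   holes inside tissue).
#' @param seed integer; fixes the image bit-exactly.
#' @return \code{synth_slide_spec} list.
#' @export
synth_slide_spec <- function(width = 448L, height = 448L, tissue_blobs = 3L,
                             blur_patches = 1L, dark_labels = 1L,
                             fat_holes = 1L, seed = 1L) {
  stopifnot(width >= 32, height >= 32)
  structure(list(width = as.integer(width), height = as.integer(height),
                 tissue_blobs = tissue_blobs, blur_patches = blur_patches,
                 dark_labels = dark_labels, fat_holes = fat_holes,
                 seed = as.integer(seed)),
            class = "synth_slide_spec")
}

rect_mask <- function(h, w, rect) {
  m <- matrix(FALSE, h, w)
  x0 <- rect[1]; y0 <- rect[2]; rw <- rect[3]; rh <- rect[4]
  if (x0 < 0 || y0 < 0 || x0 + rw > w || y0 + rh > h)
    stop_fusionmil("planted region outside image bounds")
  m[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw)] <- TRUE
  m
}

# Irregular blob: union of a few overlapping ellipses around a center.
blob_mask <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  n_ell <- sample(3:5, 1)
  ys <- row(m); xs <- col(m)
  for (i in seq_len(n_ell)) {
    ex <- cx + stats::runif(1, -0.35, 0.35) * r
    ey <- cy + stats::runif(1, -0.35, 0.35) * r
    ra <- stats::runif(1, 0.55, 1) * r
    rb <- stats::runif(1, 0.55, 1) * r
    th <- stats::runif(1, 0, pi)
    dx <- (xs - ex) * cos(th) + (ys - ey) * sin(th)
    dy <- -(xs - ex) * sin(th) + (ys - ey) * cos(th)
    m <- m | (dx / ra)^2 + (dy / rb)^2 <= 1
  }
  m
}

tissue_texture <- function(mask, base_rgb = c(0.62, 0.38, 0.55), noise_sd = 0.13) {
  n <- sum(mask)
  lapply(1:3, function(ch) {
    v <- matrix(0, nrow(mask), ncol(mask))
    v[mask] <- pmin(pmax(base_rgb[ch] + stats::rnorm(n, sd = noise_sd), 0), 1)
    v
  })
}

as_rect_list <- function(x, auto_fn) {
  if (is.numeric(x) && length(x) == 1) {
    if (x == 0) return(list())
    return(auto_fn(as.integer(x)))
  }
  x
}

#' Generate a synthetic slide image with ground-truth masks
#'
#' @param spec a \code{\link{synth_slide_spec}}.
#' @return list with \code{image} (\code{height x width x 3} array in
#'   \[0, 1\]) and \code{masks}: logical matrices \code{tissue} (sharp,
#'   artifact-free tissue), \code{blur}, \code{dark}, \code{fat}.
#' @export
gen_synthetic_slide <- function(spec) {
  stopifnot(inherits(spec, "synth_slide_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # --- tissue blobs ---
    blob <- matrix(FALSE, h, w)
    if (is.numeric(spec$tissue_blobs) && length(spec$tissue_blobs) == 1) {
      n_blobs <- as.integer(spec$tissue_blobs)
      for (i in seq_len(n_blobs)) {
        r <- stats::runif(1, 0.10, 0.16) * min(h, w)
        cx <- stats::runif(1, r * 1.4, w - r * 1.4)
        cy <- stats::runif(1, r * 1.4, h - r * 1.4)
        blob <- blob | blob_mask(h, w, cx, cy, r)
      }
    } else {
      for (rect in spec$tissue_blobs) blob <- blob | rect_mask(h, w, rect)
    }

    # --- fat holes: enclosed near-white regions inside tissue ---
    eroded <- if (any(blob)) EBImage::erode(blob * 1, EBImage::makeBrush(31, "disc")) > 0
              else blob
    fat_rects <- as_rect_list(spec$fat_holes, function(n) {
      out <- list()
      cand <- which(eroded, arr.ind = TRUE)
      for (i in seq_len(n)) {
        if (nrow(cand) == 0) break
        sz <- sample(16:28, 1)
        for (try in 1:50) {
          ctr <- cand[sample(nrow(cand), 1), ]
          x0 <- ctr[2] - 1 - sz %/% 2; y0 <- ctr[1] - 1 - sz %/% 2
          if (x0 < 0 || y0 < 0 || x0 + sz > w || y0 + sz > h) next
          if (all(eroded[(y0 + 1):(y0 + sz), (x0 + 1):(x0 + sz)])) {
            out <- c(out, list(c(x0, y0, sz, sz)))
            break
          }
        }
      }
      out
    })
    fat <- matrix(FALSE, h, w)
    for (rect in fat_rects) fat <- fat | rect_mask(h, w, rect)
    if (any(fat & !blob))
      stop_fusionmil("fat hole extends outside tissue: conflicting planted regions")

    # --- blur patches: rectangles over tissue that get Gaussian-blurred ---
    blur_rects <- as_rect_list(spec$blur_patches, function(n) {
      out <- list()
      cand <- which(blob & !fat, arr.ind = TRUE)
      for (i in seq_len(n)) {
        if (nrow(cand) == 0) break
        sz <- sample(30:50, 1)
        for (try in 1:50) {
          ctr <- cand[sample(nrow(cand), 1), ]
          x0 <- max(0, min(w - sz, ctr[2] - 1 - sz %/% 2))
          y0 <- max(0, min(h - sz, ctr[1] - 1 - sz %/% 2))
          rect <- c(x0, y0, sz, sz)
          if (!any(rect_mask(h, w, rect) & fat)) {
            out <- c(out, list(rect))
            break
          }
        }
      }
      out
    })
    blur_rect_mask <- matrix(FALSE, h, w)
    for (rect in blur_rects) blur_rect_mask <- blur_rect_mask | rect_mask(h, w, rect)
    if (any(blur_rect_mask & fat))
      stop_fusionmil("blur patch overlaps fat hole: conflicting planted regions")

    # --- dark labels: near-black rectangles on background ---
    dark_rects <- as_rect_list(spec$dark_labels, function(n) {
      out <- list()
      for (i in seq_len(n)) {
        for (try in 1:200) {
          sz_w <- sample(40:70, 1); sz_h <- sample(20:40, 1)
          x0 <- sample(0:(w - sz_w), 1); y0 <- sample(0:(h - sz_h), 1)
          rect <- c(x0, y0, sz_w, sz_h)
          rm <- rect_mask(h, w, rect)
          if (!any(rm & (blob | blur_rect_mask))) {
            out <- c(out, list(rect))
            break
          }
        }
      }
      out
    })
    dark <- matrix(FALSE, h, w)
    for (rect in dark_rects) dark <- dark | rect_mask(h, w, rect)
    if (any(dark & (blob | fat | blur_rect_mask)))
      stop_fusionmil("dark label overlaps tissue/blur/fat: conflicting planted regions")

    # --- compose image ---
    img <- array(0, dim = c(h, w, 3))
    bg <- pmin(pmax(0.96 + stats::rnorm(h * w, sd = 0.004), 0), 1)
    for (ch in 1:3) img[, , ch] <- matrix(bg, h, w)
    tex <- tissue_texture(blob)
    for (ch in 1:3) img[, , ch][blob] <- tex[[ch]][blob]
    for (ch in 1:3) img[, , ch][fat] <- pmin(pmax(
      0.94 + stats::rnorm(sum(fat), sd = 0.006), 0), 1)
    # blur the planted patches (tissue texture becomes smooth there)
    if (any(blur_rect_mask)) {
      for (ch in 1:3) {
        sm <- as.matrix(EBImage::gblur(img[, , ch], sigma = 4))
        pl <- img[, , ch]
        pl[blur_rect_mask] <- sm[blur_rect_mask]
        img[, , ch] <- pl
      }
    }
    for (ch in 1:3) img[, , ch][dark] <- pmin(pmax(
      0.04 + stats::rnorm(sum(dark), sd = 0.01), 0), 1)

    blur_gt <- blur_rect_mask & blob & !fat
    list(image = img,
         masks = list(tissue = blob & !fat & !blur_gt, blur = blur_gt,
                      dark = dark, fat = fat),
         spec = spec)
  })
}

#' Generate labeled biopsy/resection thumbnails
#'
#' Fixture for the specimen-type classifier: "biopsy" thumbnails contain
#' several small scattered tissue fragments, "resection" thumbnails one
#' large contiguous region. Labels are balanced (first half biopsy when n
#' is even).
#'
#' @param n number of thumbnails (>= 2).
#' @param seed integer seed.
#' @param size thumbnail side length in pixels (default 64).
#' @return list with \code{images} (list of \code{size x size x 3} arrays)
#'   and \code{labels} (character, "biopsy"/"resection").
#' @export
gen_specimen_thumbnails <- function(n, seed = 1L, size = 64L) {
  stopifnot(n >= 2)
  n_biopsy <- ceiling(n / 2)
  labels <- c(rep("biopsy", n_biopsy), rep("resection", n - n_biopsy))
  images <- with_seed(seed, lapply(seq_len(n), function(i) {
    h <- w <- as.integer(size)
    blob <- matrix(FALSE, h, w)
    if (labels[i] == "biopsy") {
      n_frag <- sample(6:10, 1)
      for (f in seq_len(n_frag)) {
        r <- stats::runif(1, 0.03, 0.06) * size
        blob <- blob | blob_mask(h, w, stats::runif(1, r * 2, w - r * 2),
                                 stats::runif(1, r * 2, h - r * 2), r)
      }
    } else {
      r <- stats::runif(1, 0.26, 0.34) * size
      blob <- blob | blob_mask(h, w, w / 2 + stats::runif(1, -3, 3),
                               h / 2 + stats::runif(1, -3, 3), r)
    }
    img <- array(0, dim = c(h, w, 3))
    bg <- pmin(pmax(0.96 + stats::rnorm(h * w, sd = 0.004), 0), 1)
    for (ch in 1:3) img[, , ch] <- matrix(bg, h, w)
    tex <- tissue_texture(blob)
    for (ch in 1:3) img[, , ch][blob] <- tex[[ch]][blob]
    img
  }))
  list(images = images, labels = labels)
}

#' Write an image array to PNG
#'
#' @param img \code{h x w x 3} (or \code{h x w}) array in \[0, 1\].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read an image file into an array
#'
#' Reads PNG via the png package and TIFF (including plain OME-TIFF
#' rasters) via EBImage.
#'
#' @param path image path.
#' @return numeric array \code{h x w x channels} in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_fusionmil("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(png::readPNG(path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores x,y[,c]; convert to h,w[,c]
  if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
}
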