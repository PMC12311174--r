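# Synthetic feature-bag generator.
#
# Emulates the statistical structure the MIL pipeline assumes: each slide
# is a bag of tile feature vectors; three rare, mutually exclusive fusion
# sub-labels (ROS1/ALK/NTRK); positive bags carry a signal in only a small
# fraction of their tiles (tumor tiles among benign tissue); and the three
# sub-labels share a common "fusion" feature direction plus a sub-label
# specific direction. The shared direction is what makes composite-label
# (RAN) pretraining transferable to each rare target, and its strength is
# controlled by a single scalar.

#' Specification for a synthetic feature-bag dataset
#'
#' @param n_slides number of slides (bags).
#' @param bag_size_range integer \[min, max\]; bag sizes drawn uniformly.
#' @param d feature dimension (default 384, the tile-encoder output width).
#' @param prevalence length-3 numeric, per-sub-label fraction in (0,1) for
#'   ROS1, ALK, NTRK. Positives are mutually exclusive; each slide is
#'   assigned at most one fusion.
#' @param shared_effect standardized (units of \code{noise_sd}) shift along
#'   the shared fusion direction in signal tiles of any positive bag.
#' @param specific_effect standardized shift along the sub-label specific
#'   direction.
#' @param signal_tile_frac fraction of tiles carrying signal in a positive
#'   bag. Either a scalar in (0, 1\] (every positive bag has the same
#'   fraction) or a length-2 range \code{c(min, max)} from which each
#'   positive bag draws its own fraction uniformly -- emulating the
#'   slide-to-slide variation in tumor content that makes some positive
#'   slides much harder than others. Default \code{c(0.05, 0.4)}.
#' @param noise_sd isotropic noise standard deviation.
#' @param seed integer; fixes the dataset bit-exactly.
#' @return \code{synth_bag_spec} list.
#' @export
synth_bag_spec <- function(n_slides = 500L, bag_size_range = c(20L, 50L),
                           d = 384L, prevalence = c(ROS1 = 0.01, ALK = 0.02, NTRK = 0.01),
                           shared_effect = 3, specific_effect = 1.5,
                           signal_tile_frac = c(0.05, 0.4), noise_sd = 1,
                           seed = 1L) {
  stopifnot(n_slides >= 1, length(bag_size_range) == 2,
            bag_size_range[1] >= 1, bag_size_range[2] >= bag_size_range[1],
            length(prevalence) == 3, all(prevalence > 0), all(prevalence < 1),
            sum(prevalence) < 1, noise_sd > 0)
  if (d < 4)
    stop_fusionmil("d must be at least 4 to hold the shared + three ",
                   "sub-label-specific orthonormal directions plus noise")
  if (!length(signal_tile_frac) %in% c(1L, 2L) ||
      any(signal_tile_frac <= 0) || any(signal_tile_frac > 1) ||
      signal_tile_frac[1] > signal_tile_frac[length(signal_tile_frac)])
    stop_fusionmil("signal_tile_frac must be a scalar or increasing range in (0, 1]")
  if (any(prevalence * n_slides < 1))
    stop_fusionmil("each sub-label needs expected count >= 1 (prevalence * n_slides)")
  names(prevalence) <- c("ROS1", "ALK", "NTRK")
  structure(list(n_slides = as.integer(n_slides),
                 bag_size_range = as.integer(bag_size_range), d = as.integer(d),
                 prevalence = prevalence, shared_effect = shared_effect,
                 specific_effect = specific_effect,
                 signal_tile_frac = signal_tile_frac, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_bag_spec")
}

#' Construct a feature bag
#'
#' @param slide_id character id.
#' @param features n_tiles x d numeric matrix.
#' @param coords n_tiles x 2 matrix of tile top-left (x, y) positions at
#'   working resolution.
#' @return \code{feature_bag} object.
#' @export
feature_bag <- function(slide_id, features, coords) {
  features <- as.matrix(features)
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (nrow(features) != nrow(coords))
    stop_fusionmil("feature row count must equal coordinate count")
  structure(list(slide_id = as.character(slide_id), features = features,
                 coords = coords), class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat("FeatureBag", x$slide_id, ":", nrow(x$features), "tiles x",
      ncol(x$features), "features\n")
  invisible(x)
}

# Default synthetic tile layout: tiles on a square-ish grid, 224 px pitch.
grid_coords <- function(n_tiles, tile_size = 224L) {
  ncol_grid <- max(1L, ceiling(sqrt(n_tiles)))
  idx <- seq_len(n_tiles) - 1L
  cbind(x = (idx %% ncol_grid) * tile_size,
        y = (idx %/% ncol_grid) * tile_size)
}

#' Generate a synthetic feature-bag dataset
#'
#' Draws four fixed orthonormal signal directions per seed (one shared
#' "fusion" direction and one per sub-label), assigns each slide at most
#' one fusion sub-label by a multinomial draw at the configured
#' prevalences, and fills bags with isotropic Gaussian noise. In a
#' positive bag, a \code{signal_tile_frac} fraction of tiles additionally
#' receive \code{shared_effect * noise_sd} along the shared direction plus
#' \code{specific_effect * noise_sd} along the sub-label's own direction.
#'
#' @param spec a \code{\link{synth_bag_spec}}.
#' @return list with \code{bags} (list of \code{feature_bag}; each carries
#'   a \code{signal_tiles} attribute with the ground-truth signal tile
#'   indices), \code{manifest} (data.frame: slide_id, ROS1, ALK, NTRK,
#'   specimen_type), \code{directions} (d x 4 orthonormal matrix), and the
#'   \code{spec}.
#' @export
gen_bag_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_bag_spec"))
  with_seed(spec$seed, {
    d <- spec$d
    # fixed orthonormal directions: shared, ROS1, ALK, NTRK
    U <- qr.Q(qr(matrix(stats::rnorm(d * 4), d, 4)))
    colnames(U) <- c("shared", "ROS1", "ALK", "NTRK")
    labs <- c("ROS1", "ALK", "NTRK", "none")
    probs <- c(spec$prevalence, 1 - sum(spec$prevalence))
    assign_lab <- sample(labs, spec$n_slides, replace = TRUE, prob = probs)
    ids <- sprintf("slide_%04d", seq_len(spec$n_slides))
    bag_sizes <- sample(seq(spec$bag_size_range[1], spec$bag_size_range[2]),
                        spec$n_slides, replace = TRUE)
    bags <- vector("list", spec$n_slides)
    for (i in seq_len(spec$n_slides)) {
      n_t <- bag_sizes[i]
      X <- matrix(stats::rnorm(n_t * d, sd = spec$noise_sd), n_t, d)
      sig_idx <- integer(0)
      if (assign_lab[i] != "none") {
        frac <- if (length(spec$signal_tile_frac) == 2)
          stats::runif(1, spec$signal_tile_frac[1], spec$signal_tile_frac[2])
        else spec$signal_tile_frac
        n_sig <- max(1L, ceiling(frac * n_t))
        sig_idx <- sort(sample(n_t, n_sig))
        shift <- spec$noise_sd *
          (spec$shared_effect * U[, "shared"] +
             spec$specific_effect * U[, assign_lab[i]])
        X[sig_idx, ] <- X[sig_idx, , drop = FALSE] +
          matrix(shift, n_sig, d, byrow = TRUE)
      }
      bag <- feature_bag(ids[i], X, grid_coords(n_t))
      attr(bag, "signal_tiles") <- sig_idx
      bags[[i]] <- bag
    }
    manifest <- data.frame(slide_id = ids,
                           ROS1 = assign_lab == "ROS1",
                           ALK = assign_lab == "ALK",
                           NTRK = assign_lab == "NTRK",
                           specimen_type = sample(c("biopsy", "resection"),
                                                  spec$n_slides, replace = TRUE),
                           stringsAsFactors = FALSE)
    list(bags = stats::setNames(bags, ids), manifest = manifest,
         directions = U, spec = spec)
  })
}

#' Write / read a feature-bag dataset directory
#'
#' Plain-text bag container: \code{manifest.csv} plus, per slide,
#' \code{<slide_id>.features.csv} (n_tiles x d) and
#' \code{<slide_id>.coords.csv} (n_tiles x 2). One directory plays the
#' role of one bag container file; the logical schema (per-slide group
#' holding a feature matrix and its tile coordinates) is unchanged.
#'
#' @param dataset list with \code{bags} and \code{manifest} as returned by
#'   \code{\link{gen_bag_dataset}}.
#' @param dir target directory (created if missing).
#' @return \code{write_bag_dataset} returns \code{dir} invisibly;
#'   \code{read_bag_dataset} returns a list with \code{bags} and
#'   \code{manifest}.
#' @export
write_bag_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (bag in dataset$bags) {
    base <- file.path(dir, bag$slide_id)
    utils::write.csv(as.data.frame(bag$features),
                     paste0(base, ".features.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(bag$coords),
                     paste0(base, ".coords.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_bag_dataset
#' @export
read_bag_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  bags <- lapply(manifest$slide_id, function(id) {
    base <- file.path(dir, id)
    feature_bag(id,
                as.matrix(utils::read.csv(paste0(base, ".features.csv"))),
                as.matrix(utils::read.csv(paste0(base, ".coords.csv"))))
  })
  list(bags = stats::setNames(bags, manifest$slide_id), manifest = manifest)
}
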