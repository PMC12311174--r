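#' Compose the RAN composite fusion label
#'
#' Adds (or recomputes) the composite \code{RAN} column of a label table:
#' a sample is RAN-positive if it carries any ROS1, ALK, or NTRK fusion.
#' Pooling the three rare, biologically related fusions into one label
#' gives the first training stage roughly four times as many positive
#' slides as the rarest single fusion, which is the point of the two-step
#' training strategy.
#'
#' @param table data.frame with logical/0-1 columns \code{ROS1}, \code{ALK},
#'   \code{NTRK} and a unique \code{slide_id} column.
#' @return The same data.frame with a logical \code{RAN} column; no other
#'   column is modified.
#' @examples
#' tab <- data.frame(slide_id = c("a", "b"), ROS1 = c(TRUE, FALSE),
#'                   ALK = FALSE, NTRK = FALSE)
#' compose_ran_label(tab)$RAN
#' @export
compose_ran_label <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("slide_id", "ROS1", "ALK", "NTRK")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop_fusionmil("label table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$slide_id))
    stop_fusionmil("slide_id values must be unique")
  for (col in c("ROS1", "ALK", "NTRK")) {
    v <- table[[col]]
    if (anyNA(v)) {
      bad <- table$slide_id[which(is.na(v))[1]]
      stop_fusionmil("missing ", col, " value for slide_id '", bad, "'")
    }
    table[[col]] <- as.logical(v)
  }
  table$RAN <- table$ROS1 | table$ALK | table$NTRK
  table
}

#' Carve an independent holdout set
#'
#' Reserves a random fraction of slides for final evaluation before any
#' training (including self-supervised pretraining) touches the data. The
#' draw is plain random sampling, seed-deterministic.
#'
#' @param table label table with a \code{slide_id} column.
#' @param frac fraction of slides to hold out (default 0.15).
#' @param seed integer seed fixing the partition.
#' @return list with \code{cv_ids} and \code{holdout_ids} character vectors;
#'   disjoint, union = all slide ids, \code{length(holdout_ids) == round(frac * n)}.
#' @export
make_holdout <- function(table, frac = 0.15, seed = 1L) {
  stopifnot(is.data.frame(table), frac > 0, frac < 1)
  ids <- as.character(table$slide_id)
  n <- length(ids)
  if (n < 2) stop_fusionmil("need at least 2 slides to carve a holdout set")
  n_hold <- round(frac * n)
  holdout <- with_seed(seed, sample(ids, n_hold))
  list(cv_ids = setdiff(ids, holdout), holdout_ids = holdout)
}

# Largest-remainder apportionment of `total` into parts proportional to
# `fractions`. Preserves the total exactly.
apportion <- function(total, fractions) {
  raw <- total * fractions
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Draw stratified train/validation/test splits
#'
#' Draws \code{k} independent stratified splits (not a k-fold partition) of
#' the cross-validation cohort. Within each split, each class of the
#' stratification label is apportioned across train/val/test by
#' largest-remainder rounding, so class proportions are within one sample
#' of the stratified targets and totals are preserved.
#'
#' @param cv_table label table restricted to the CV cohort.
#' @param k number of independent splits (default 5).
#' @param fractions train/val/test fractions summing to 1 (default 60/20/20).
#' @param stratify name of the logical column to stratify on (default "RAN").
#' @param seed integer seed.
#' @return A \code{split_plan} list: \code{folds} (each with
#'   \code{train_ids}, \code{val_ids}, \code{test_ids}), plus the seed and
#'   stratify label. Downsampled training lists are added by
#'   \code{\link{downsample_negatives}} or \code{\link{build_split_plan}}.
#' @export
make_cv_splits <- function(cv_table, k = 5L, fractions = c(0.6, 0.2, 0.2),
                           stratify = "RAN", seed = 1L) {
  stopifnot(is.data.frame(cv_table), k >= 1, length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_fusionmil("train/val/test fractions must sum to 1")
  if (!stratify %in% names(cv_table))
    stop_fusionmil("stratification column '", stratify, "' not found")
  y <- as.logical(cv_table[[stratify]])
  ids <- as.character(cv_table$slide_id)
  if (length(unique(y)) < 2)
    stop_fusionmil("both classes must be present to stratify")
  if (sum(y) < k)
    warning("fewer positive samples (", sum(y), ") than splits (", k, ")")
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- with_seed(child_seed(seed, f), {
      parts <- list(train_ids = character(), val_ids = character(),
                    test_ids = character())
      for (cls in c(TRUE, FALSE)) {
        cls_ids <- sample(ids[y == cls])
        counts <- apportion(length(cls_ids), fractions)
        parts$train_ids <- c(parts$train_ids, cls_ids[seq_len(counts[1])])
        parts$val_ids <- c(parts$val_ids, cls_ids[counts[1] + seq_len(counts[2])])
        parts$test_ids <- c(parts$test_ids,
                            cls_ids[counts[1] + counts[2] + seq_len(counts[3])])
      }
      parts
    })
    folds[[f]] <- fold
  }
  structure(list(folds = folds, k = as.integer(k), fractions = fractions,
                 stratify_label = stratify, seed = as.integer(seed)),
            class = "split_plan")
}

#' Downsample training negatives
#'
#' Keeps every positive training slide and randomly downsamples negatives
#' to at most \code{ratio} times the positive count (all negatives are kept
#' if there are fewer than that). Drawn once per fold and fixed across
#' epochs; validation and test sets are never touched.
#'
#' @param train_ids character vector of training slide ids.
#' @param labels named logical vector (names = slide ids) of the target label.
#' @param ratio maximum negative:positive ratio (default 5).
#' @param seed integer seed.
#' @return character vector of retained slide ids (positives first).
#' @export
downsample_negatives <- function(train_ids, labels, ratio = 5, seed = 1L) {
  stopifnot(ratio > 0)
  y <- labels[train_ids]
  if (anyNA(y)) stop_fusionmil("labels missing for some training ids")
  pos <- train_ids[y]
  neg <- train_ids[!y]
  if (length(pos) == 0) stop_fusionmil("no positive samples in training set")
  n_keep <- min(length(neg), floor(ratio * length(pos)))
  kept_neg <- with_seed(seed, sample(neg, n_keep))
  c(pos, kept_neg)
}

#' Build a complete split plan
#'
#' Convenience wrapper: carves the holdout, draws \code{k} stratified
#' splits of the remaining CV cohort, and attaches per-fold downsampled
#' training id lists for the stratification label.
#'
#' @inheritParams make_cv_splits
#' @param table full label table (with RAN composed).
#' @param holdout_frac holdout fraction (default 0.15).
#' @param ratio negative downsampling ratio (default 5).
#' @param seed integer seed.
#' @return \code{split_plan} with \code{holdout_ids} and, per fold,
#'   \code{downsampled_train_ids}.
#' @export
build_split_plan <- function(table, holdout_frac = 0.15, k = 5L,
                             fractions = c(0.6, 0.2, 0.2), stratify = "RAN",
                             ratio = 5, seed = 1L) {
  hold <- make_holdout(table, holdout_frac, seed = child_seed(seed, 0L))
  cv_table <- table[table$slide_id %in% hold$cv_ids, , drop = FALSE]
  plan <- make_cv_splits(cv_table, k = k, fractions = fractions,
                         stratify = stratify, seed = child_seed(seed, 1L))
  labels <- stats::setNames(as.logical(table[[stratify]]),
                            as.character(table$slide_id))
  for (f in seq_along(plan$folds)) {
    plan$folds[[f]]$downsampled_train_ids <- downsample_negatives(
      plan$folds[[f]]$train_ids, labels, ratio = ratio,
      seed = child_seed(seed, 100L + f))
  }
  plan$holdout_ids <- hold$holdout_ids
  plan$ratio <- ratio
  plan
}

#' Serialize / restore a split plan
#'
#' @param plan a \code{split_plan}.
#' @param path JSON file path.
#' @return \code{write_split_plan} returns \code{path} invisibly;
#'   \code{read_split_plan} returns the restored \code{split_plan}.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan$folds <- lapply(seq_len(nrow_or_len(plan$folds)), function(i) {
    f <- if (is.data.frame(plan$folds)) lapply(plan$folds, `[[`, i) else plan$folds[[i]]
    lapply(f, as.character)
  })
  structure(plan, class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", length(x$folds), "stratified splits on", x$stratify_label, "\n")
  if (!is.null(x$holdout_ids))
    cat("  holdout:", length(x$holdout_ids), "slides\n")
  f <- x$folds[[1]]
  cat("  fold sizes (train/val/test):", length(f$train_ids), "/",
      length(f$val_ids), "/", length(f$test_ids), "\n")
  if (!is.null(f$downsampled_train_ids))
    cat("  downsampled train size:", length(f$downsampled_train_ids), "\n")
  invisible(x)
}
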