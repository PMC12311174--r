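# Diagnostic metrics for rare-positive screening. PPA/NPA are the
# diagnostic-terminology names for sensitivity/specificity; PPV is
# precision. All thresholded metrics use the rule "predict positive iff
# score >= t" (ties count as positive).

#' Confusion counts at a threshold
#'
#' @param scores numeric predicted probabilities in \[0, 1\].
#' @param labels binary (0/1 or logical) true labels.
#' @param t decision threshold (default 0.5); prediction positive iff
#'   \code{score >= t}.
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusion_at_threshold <- function(scores, labels, t = 0.5) {
  if (length(scores) != length(labels))
    stop_fusionmil("scores and labels have different lengths")
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= t)
  c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
    TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' ROC AUC via the Mann-Whitney statistic
#'
#' Rank-based computation equal to the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @inheritParams confusion_at_threshold
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_fusionmil("ROC AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC
#'
#' Step-wise integration of precision over the distinct recall points,
#' sweeping the threshold from high to low (the convention used for
#' average precision): \code{sum((R_i - R_{i-1}) * P_i)}.
#'
#' @inheritParams confusion_at_threshold
#' @return PR AUC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (sum(y) == 0 || sum(y) == length(y))
    stop_fusionmil("PR AUC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Summary diagnostic metrics
#'
#' Computes ROC AUC (Mann-Whitney), PR AUC, and the thresholded metrics
#' accuracy, PPA (sensitivity), PPV (precision), NPA (specificity) and F1
#' from the confusion counts at threshold \code{t}.
#'
#' @inheritParams confusion_at_threshold
#' @return \code{metrics_report} list: \code{roc_auc, pr_auc, accuracy,
#'   PPA, PPV, NPA, F1, confusion, threshold, n}. With single-class labels
#'   the AUCs are \code{NA} and \code{auc_undefined} is set.
#' @export
summary_metrics <- function(scores, labels, t = 0.5) {
  if (length(scores) != length(labels))
    stop_fusionmil("scores and labels have different lengths")
  y <- as.logical(labels)
  cm <- confusion_at_threshold(scores, labels, t)
  one_class <- length(unique(y)) < 2
  rep <- list(
    roc_auc = if (one_class) NA_real_ else roc_auc(scores, y),
    pr_auc = if (one_class) NA_real_ else pr_auc(scores, y),
    accuracy = (cm["TP"] + cm["TN"]) / length(y),
    PPA = unname(cm["TP"] / max(cm["TP"] + cm["FN"], 1L)),
    PPV = if (cm["TP"] + cm["FP"] > 0) unname(cm["TP"] / (cm["TP"] + cm["FP"])) else NA_real_,
    NPA = unname(cm["TN"] / max(cm["TN"] + cm["FP"], 1L)),
    confusion = cm, threshold = t, n = length(y),
    auc_undefined = one_class)
  rep$accuracy <- unname(rep$accuracy)
  p <- rep$PPV; r <- rep$PPA
  rep$F1 <- if (!is.na(p) && (p + r) > 0) 2 * p * r / (p + r) else 0
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "ROC AUC %.3f | PR AUC %.3f | Acc %.3f | PPA %.3f | PPV %.3f | F1 %.3f | NPA %.3f (t=%.2f, n=%d)\n",
    x$roc_auc, x$pr_auc, x$accuracy, x$PPA, x$PPV, x$F1, x$NPA, x$threshold, x$n))
  invisible(x)
}

#' Screening trade-off curve
#'
#' Sweeps the decision threshold over all distinct scores plus boundary
#' points and records, at each threshold, the false-negative rate FN/n,
#' the true-negative rate TN/n, and PPA. These are the axes of the
#' screening trade-off plot: how many fusions would be missed versus how
#' many confirmatory tests would be saved at each operating point.
#'
#' @inheritParams confusion_at_threshold
#' @return \code{tradeoff_curve} data.frame with columns
#'   \code{threshold, fn_rate, tn_rate, ppa}.
#' @export
tradeoff_curve <- function(scores, labels) {
  y <- as.logical(labels)
  if (sum(y) == 0 || sum(!y) == 0)
    stop_fusionmil("trade-off curve needs both classes present")
  ts <- sort(unique(c(0, scores, max(scores) + 1e-9, 1)))
  n <- length(y)
  rows <- lapply(ts, function(t) {
    cm <- confusion_at_threshold(scores, y, t)
    data.frame(threshold = t, fn_rate = cm["FN"] / n, tn_rate = cm["TN"] / n,
               ppa = cm["TP"] / (cm["TP"] + cm["FN"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tradeoff_curve", "data.frame")
  out
}

#' Normalized per-class probability histogram
#'
#' @inheritParams confusion_at_threshold
#' @param bins number of equal-width bins covering \[0, 1\].
#' @return list with \code{breaks} (length bins + 1) and per-class mass
#'   vectors \code{positive} and \code{negative}, each summing to 1 (empty
#'   classes give an empty numeric vector).
#' @export
probability_histogram <- function(scores, labels, bins = 20L) {
  stopifnot(bins >= 1)
  y <- as.logical(labels)
  breaks <- seq(0, 1, length.out = bins + 1L)
  mass <- function(s) {
    if (length(s) == 0) return(numeric(0))
    h <- hist(pmin(pmax(s, 0), 1), breaks = breaks, plot = FALSE)
    h$counts / length(s)
  }
  list(breaks = breaks, positive = mass(scores[y]), negative = mass(scores[!y]))
}

#' Aggregate metric reports across folds
#'
#' @param reports list of \code{metrics_report} objects.
#' @return data.frame with one row per metric and columns \code{mean} and
#'   \code{sd} (sample standard deviation; 0 with \code{sd_undefined} flag
#'   for a single report).
#' @export
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 1)
  metrics <- c("roc_auc", "pr_auc", "accuracy", "PPA", "PPV", "F1", "NPA")
  vals <- sapply(metrics, function(m) sapply(reports, function(r) as.numeric(r[[m]])))
  vals <- matrix(vals, nrow = length(reports), dimnames = list(NULL, metrics))
  out <- data.frame(
    metric = metrics,
    mean = colMeans(vals, na.rm = TRUE),
    sd = if (nrow(vals) > 1) apply(vals, 2, stats::sd, na.rm = TRUE) else 0)
  attr(out, "sd_undefined") <- nrow(vals) < 2
  rownames(out) <- NULL
  out
}

#' Specimen-type stratified metric report
#'
#' Computes \code{\link{summary_metrics}} on all cases and on each
#' specimen stratum (e.g. biopsy-only and resection-only subsets).
#'
#' @inheritParams confusion_at_threshold
#' @param strata character vector of stratum labels aligned with scores.
#' @return named list of \code{metrics_report}: \code{ALL} plus one entry
#'   per stratum; empty strata are omitted with a warning, single-class
#'   strata carry the \code{auc_undefined} flag.
#' @export
stratified_report <- function(scores, labels, strata, t = 0.5) {
  if (length(strata) != length(scores))
    stop_fusionmil("strata must align with scores")
  out <- list(ALL = summary_metrics(scores, labels, t))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) == 0) {
      warning("empty stratum '", s, "' omitted")
      next
    }
    out[[s]] <- summary_metrics(scores[idx], labels[idx], t)
  }
  out
}

#' Evaluation plots
#'
#' Base-graphics renderings of the standard evaluation panels: ROC curve,
#' precision-recall curve, per-class probability histogram, and the
#' screening trade-off plot (blue: PPA vs FN/n; red: TN/n vs FN/n).
#'
#' @inheritParams confusion_at_threshold
#' @param which one of "roc", "pr", "histogram", "tradeoff".
#' @param ... passed to the underlying plot call.
#' @return invisibly, the data underlying the plot.
#' @export
plot_evaluation <- function(scores, labels, which = c("roc", "pr", "histogram", "tradeoff"), ...) {
  which <- match.arg(which)
  y <- as.logical(labels)
  if (which == "roc") {
    ts <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    pts <- t(vapply(ts, function(t) {
      cm <- confusion_at_threshold(scores, y, t)
      c(fpr = cm["FP"] / max(sum(!y), 1L), tpr = cm["TP"] / max(sum(y), 1L))
    }, c(fpr = 0, tpr = 0)))
    plot(pts[, 1], pts[, 2], type = "l", xlab = "1 - NPA (FPR)",
         ylab = "PPA (TPR)", main = sprintf("ROC (AUC = %.3f)", roc_auc(scores, y)), ...)
    abline(0, 1, lty = 3, col = "grey")
    return(invisible(pts))
  }
  if (which == "pr") {
    o <- order(scores, decreasing = TRUE)
    yy <- as.integer(y[o])
    tp <- cumsum(yy); fp <- cumsum(1 - yy)
    rec <- tp / sum(yy); prec <- tp / (tp + fp)
    plot(rec, prec, type = "l", xlab = "PPA (recall)", ylab = "PPV (precision)",
         ylim = c(0, 1), main = sprintf("PR (AUC = %.3f)", pr_auc(scores, y)), ...)
    return(invisible(data.frame(recall = rec, precision = prec)))
  }
  if (which == "histogram") {
    h <- probability_histogram(scores, y, ...)
    mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
    w <- diff(h$breaks)[1] * 0.42
    plot(NULL, xlim = c(0, 1), ylim = c(0, max(c(h$positive, h$negative, 0.01))),
         xlab = "predicted probability", ylab = "normalized mass",
         main = "Probability histogram")
    if (length(h$negative)) rect(mids - w, 0, mids, h$negative, col = "firebrick", border = NA)
    if (length(h$positive)) rect(mids, 0, mids + w, h$positive, col = "steelblue", border = NA)
    legend("top", fill = c("steelblue", "firebrick"), legend = c("positive", "negative"), bty = "n")
    return(invisible(h))
  }
  tc <- tradeoff_curve(scores, y)
  plot(tc$fn_rate, tc$ppa, type = "l", col = "steelblue", ylim = c(0, 1),
       xlab = "FN / n", ylab = "PPA (blue) and TN/n (red)",
       main = "Screening trade-off", ...)
  lines(tc$fn_rate, tc$tn_rate, col = "firebrick")
  invisible(tc)
}
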