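# Training of the MIL aggregator: class-weighted binary cross-entropy,
# direct training on a target fusion label, and the two-step strategy --
# pretrain on the composite RAN label, then fine-tune on the rare target
# at a ten-fold smaller learning rate using the same fold's splits.

#' Class-weighted binary cross-entropy
#'
#' \code{-[W y log p + (1 - y) log(1 - p)]}, averaged over elements.
#' \code{W = 1} recovers the standard cross-entropy; \code{W > 1} penalizes
#' missed positives more, trading NPA/accuracy for PPA on rare-positive
#' screening tasks.
#'
#' @param p predicted probabilities in (0, 1); values outside are clamped
#'   to \code{[eps, 1 - eps]} with a message.
#' @param y binary labels.
#' @param W positive-class weight (> 0; default 5).
#' @param eps clamping epsilon.
#' @return scalar mean loss (non-negative).
#' @export
weighted_bce <- function(p, y, W = 5, eps = 1e-12) {
  stopifnot(W > 0, length(p) == length(y))
  y <- as.numeric(as.logical(y))
  if (any(p <= 0 | p >= 1)) {
    message("weighted_bce: probabilities clamped to (0, 1)")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  mean(-(W * y * log(p) + (1 - y) * log(1 - p)))
}

# d(weighted_bce)/d(logit) for p = sigmoid(logit), one sample.
wbce_dlogit <- function(p, y, W) {
  if (y > 0) W * (p - 1) else p
}

#' Training configuration
#'
#' @param target_label one of "ROS1", "ALK", "NTRK", "RAN".
#' @param pos_weight positive-class loss weight W (default 5; the sweep of
#'   interest is \{5, 10, 20, 30\}).
#' @param lr learning rate for direct (or stage-1) training.
#' @param finetune_lr_factor stage-2 learning-rate multiplier (default
#'   0.1: fine-tuning runs at a ten-times smaller learning rate).
#' @param epochs training epochs over the downsampled training set.
#' @param batch_size bags per optimizer step (gradients averaged).
#' @param weight_decay decoupled (AdamW-style) weight-decay coefficient
#'   (default 0.01); keeps the tiny aggregator's logits from saturating
#'   on desk-scale training sets.
#' @param eval_every validation-AUC evaluation cadence in epochs.
#' @param ratio negative downsampling ratio for the training set.
#' @param seed integer seed for shuffling, downsampling and dropout.
#' @return \code{train_config} list.
#' @export
train_config <- function(target_label = "RAN", pos_weight = 5, lr = 1e-3,
                         finetune_lr_factor = 0.1, epochs = 6L,
                         batch_size = 8L, eval_every = 1L, ratio = 5,
                         weight_decay = 0.01, seed = 1L) {
  stopifnot(target_label %in% c("ROS1", "ALK", "NTRK", "RAN"), pos_weight > 0,
            lr >= 0, epochs >= 0, batch_size >= 1, eval_every >= 1, ratio > 0)
  structure(list(target_label = target_label, pos_weight = pos_weight,
                 lr = lr, finetune_lr_factor = finetune_lr_factor,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every), ratio = ratio,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Select the checkpoint with the best validation AUC
#'
#' @param trace a training trace (list with \code{val_auc}).
#' @return 0-based index of the evaluation step attaining the maximum
#'   validation AUC; ties resolve to the earliest step.
#' @export
select_checkpoint <- function(trace) {
  auc <- if (is.list(trace)) trace$val_auc else trace
  if (length(auc) == 0) stop_fusionmil("empty training trace")
  which.max(auc) - 1L
}

label_vector <- function(manifest, label) {
  tab <- compose_ran_label(manifest)
  stats::setNames(as.logical(tab[[label]]), as.character(tab$slide_id))
}

# Shared training loop. `model` comes in initialized (or pretrained);
# trains on `train_ids` with weighted BCE at `lr`, evaluating ROC AUC on
# `val_ids` every `eval_every` epochs, and returns the model rolled back
# to the best-validation checkpoint together with its trace.
train_mil_loop <- function(model, bags, labels, train_ids, val_ids, config,
                           lr) {
  y_val <- labels[val_ids]
  if (length(unique(y_val)) < 2)
    stop_fusionmil("validation set must contain both classes")
  eval_val <- function(m) {
    p <- vapply(val_ids, function(id) forward_bag(m, bags[[id]])$probability, 0)
    roc_auc(p, y_val)
  }
  W <- config$pos_weight
  opt <- adam_init(model$params, lr = lr,
                   weight_decay = config$weight_decay %||% 0)
  val_auc <- numeric(0)
  eval_steps <- integer(0)
  snapshots <- list()
  loss_curve <- numeric(0)
  with_seed(child_seed(config$seed, 7L), {
    # step 0: evaluate the incoming model so zero-epoch training is honest
    val_auc <- eval_val(model)
    eval_steps <- 0L
    snapshots <- list(model$params)
    step <- 0L
    if (config$epochs > 0) for (epoch in seq_len(config$epochs)) {
      order_ids <- sample(train_ids)
      epoch_loss <- 0
      n_batches <- ceiling(length(order_ids) / config$batch_size)
      for (b in seq_len(n_batches)) {
        idx <- ((b - 1L) * config$batch_size + 1L):min(b * config$batch_size,
                                                       length(order_ids))
        batch_ids <- order_ids[idx]
        gacc <- NULL
        bloss <- 0
        # batch gradients are normalized by total example weight, not
        # count, so the optimizer step does not scale with W
        batch_w <- sum(ifelse(labels[batch_ids], W, 1))
        for (id in batch_ids) {
          X <- bags[[id]]$features
          mask <- NULL
          if (model$config$dropout > 0)
            mask <- matrix(stats::rbinom(nrow(X), 1, 1 - model$config$dropout),
                           nrow(X), model$config$d_model)
          fw <- agg_forward(model, X, want_cache = TRUE, drop_mask = mask)
          yv <- as.numeric(labels[[id]])
          bloss <- bloss + weighted_bce(fw$probability, yv, W)
          dlogit <- wbce_dlogit(fw$probability, yv, W) / batch_w
          g <- agg_backward(model, fw$cache, dlogit)$grads
          gacc <- if (is.null(gacc)) g else tree_map2(`+`, gacc, g)
        }
        st <- adam_step(opt, model$params, gacc)
        opt <- st$state
        model$params <- st$params
        epoch_loss <- epoch_loss + bloss / length(batch_ids)
        step <- step + 1L
      }
      loss_curve <- c(loss_curve, epoch_loss / n_batches)
      if (epoch %% config$eval_every == 0L || epoch == config$epochs) {
        val_auc <- c(val_auc, eval_val(model))
        eval_steps <- c(eval_steps, step)
        snapshots <- c(snapshots, list(model$params))
      }
    }
  })
  sel <- select_checkpoint(list(val_auc = val_auc))
  model$params <- snapshots[[sel + 1L]]
  model$trace <- list(val_auc = val_auc, eval_steps = eval_steps,
                      loss = loss_curve, selected_step = sel,
                      label = config$target_label, pos_weight = W, lr = lr)
  model
}

#' Direct training on a target fusion label
#'
#' Downsamples the fold's training negatives to \code{ratio} times the
#' positives of the target label, trains the aggregator with weighted BCE
#' at \code{config$lr}, and evaluates validation ROC AUC every
#' \code{eval_every} epochs on the untouched validation set. The returned
#' model is rolled back to the best-validation checkpoint.
#'
#' @param bags named list of \code{\link{feature_bag}}s.
#' @param manifest label table (slide_id, ROS1, ALK, NTRK, ...).
#' @param fold one fold of a \code{\link{make_cv_splits}} plan (list with
#'   \code{train_ids} and \code{val_ids}).
#' @param config a \code{\link{train_config}}.
#' @param agg_config an \code{\link{aggregator_config}}; its \code{d_in}
#'   must match the bag feature dimension.
#' @return trained \code{mil_model}; \code{model$trace} holds the
#'   validation-AUC trace, loss curve and selected checkpoint step.
#' @export
train_direct <- function(bags, manifest, fold, config,
                         agg_config = aggregator_config()) {
  stopifnot(inherits(config, "train_config"))
  labels <- label_vector(manifest, config$target_label)
  train_ids <- downsample_negatives(fold$train_ids, labels, ratio = config$ratio,
                                    seed = child_seed(config$seed, 11L))
  model <- build_aggregator(agg_config)
  train_mil_loop(model, bags, labels, train_ids, fold$val_ids, config,
                 lr = config$lr)
}

#' Two-step training: RAN pretrain, then target fine-tune
#'
#' Stage 1 trains on the composite RAN label (any ROS1/ALK/NTRK fusion),
#' which has roughly four times as many positives as the rarest target.
#' The best-validation RAN checkpoint then initializes stage 2, which
#' fine-tunes on the target label using the same fold's splits at a
#' learning rate \code{finetune_lr_factor} (default 0.1) times the stage-1
#' rate. With zero stage-2 epochs the returned model is bitwise the
#' stage-1 checkpoint.
#'
#' @inheritParams train_direct
#' @param ran_config \code{\link{train_config}} for stage 1 (its
#'   \code{target_label} should be "RAN").
#' @param target_config \code{\link{train_config}} for stage 2 (the rare
#'   target label).
#' @return trained \code{mil_model} with \code{model$trace} from stage 2
#'   and \code{model$ran_trace} from stage 1.
#' @export
train_finetune <- function(bags, manifest, fold, ran_config, target_config,
                           agg_config = aggregator_config()) {
  stage1 <- train_direct(bags, manifest, fold, ran_config, agg_config)
  if (target_config$epochs == 0L) {
    stage1$ran_trace <- stage1$trace
    return(stage1)
  }
  labels <- label_vector(manifest, target_config$target_label)
  train_ids <- downsample_negatives(fold$train_ids, labels,
                                    ratio = target_config$ratio,
                                    seed = child_seed(target_config$seed, 13L))
  lr2 <- target_config$lr * target_config$finetune_lr_factor
  model <- train_mil_loop(stage1, bags, labels, train_ids, fold$val_ids,
                          target_config, lr = lr2)
  model$ran_trace <- stage1$trace
  model
}
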