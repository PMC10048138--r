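# Optimisation loop: momentum SGD on the weighted pixel loss, step
# learning-rate decay, early stopping on validation patience, best-model
# selection by validation loss.

#' Training configuration
#'
#' Defaults mirror the reference regimen: initial learning rate 1e-3, rate
#' divided by 3 every 10 epochs, at most 50 epochs, mini-batch 10, validation
#' patience 4. Momentum 0.9 is the conventional SGDM default.
#'
#' @param initial_lr initial learning rate.
#' @param lr_drop_period epochs between learning-rate drops.
#' @param lr_drop_factor multiplicative factor in (0, 1] applied at each drop
#'   (the printed drop factor "3" means divide by 3, i.e. 1/3).
#' @param max_epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param validation_patience consecutive non-improving validations before
#'   stopping.
#' @param momentum SGDM momentum.
#' @param seed seed for shuffling (and any augmentation draws).
#' @param class_weights a `class_weights` vector from [median_frequency_weights()] or `NULL` for unweighted
#'   training.
#' @param augment logical; apply random rotation/scaling to training batches.
#' @return object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-3, lr_drop_period = 10L,
                         lr_drop_factor = 1 / 3, max_epochs = 50L,
                         batch_size = 10L, validation_patience = 4L,
                         momentum = 0.9, seed = 1L, class_weights = NULL,
                         augment = FALSE) {
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stop("train_config: lr_drop_factor must be in (0, 1]")
  if (validation_patience < 1) stop("train_config: patience must be >= 1")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  structure(list(initial_lr = initial_lr, lr_drop_period = as.integer(lr_drop_period),
                 lr_drop_factor = lr_drop_factor, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 validation_patience = as.integer(validation_patience),
                 momentum = momentum, seed = as.integer(seed),
                 class_weights = class_weights, augment = isTRUE(augment)),
            class = "train_config")
}

#' Step learning-rate schedule
#'
#' `initial_lr * lr_drop_factor ^ floor(epoch / lr_drop_period)` for a
#' 0-based epoch index: epochs 0-9 run at the initial rate, each subsequent
#' period multiplies by the drop factor.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  cfg$initial_lr * cfg$lr_drop_factor^(epoch %/% cfg$lr_drop_period)
}

#' Early-stopping point of a validation-loss sequence
#'
#' Counts consecutive validations without a strict improvement over the best
#' loss so far; training stops after the first validation at which the count
#' reaches `patience`.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving validations tolerated.
#' @return list: `stop_epoch` (1-based index of the last evaluated epoch, or
#'   `length(val_losses)` if never triggered), `best_epoch`, and `triggered`.
#' @export
stopping_point <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- 0L
  bad <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]
      best_epoch <- i
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience)
        return(list(stop_epoch = i, best_epoch = best_epoch, triggered = TRUE))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch, triggered = FALSE)
}

# stack a list of labeled images into [H, W, 1, N] pixels + [H, W, N] labels
stack_images <- function(images, augment = FALSE) {
  if (augment) images <- lapply(images, augment_image)
  h <- nrow(images[[1]]$pixels); w <- ncol(images[[1]]$pixels)
  n <- length(images)
  px <- array(0, dim = c(h, w, 1L, n))
  lb <- array(0L, dim = c(h, w, n))
  for (i in seq_len(n)) {
    px[, , 1L, i] <- images[[i]]$pixels
    lb[, , i] <- images[[i]]$labels
  }
  list(pixels = px, labels = lb)
}

eval_split <- function(model, images, weights) {
  b <- stack_images(images, augment = FALSE)
  scores <- nn_forward(model, b$pixels, training = FALSE)
  loss <- wce_loss_grad(scores, b$labels, weights, want_grad = FALSE)$loss
  pred <- apply(scores, 4, scores_to_labels, simplify = FALSE)
  gts <- lapply(seq_along(images), function(i) b$labels[, , i])
  cm <- confusion_matrix(gts, pred, n = dim(scores)[3])
  list(loss = loss, gacc = global_accuracy(cm), cm = cm)
}

#' Train a segmentation model on a phantom cohort
#'
#' Momentum SGD on the (optionally class-weighted) pixel-wise cross-entropy
#' over shuffled training batches; validation loss and global accuracy are
#' evaluated once per epoch. Stops at `max_epochs` or when the validation
#' loss has not strictly improved for `validation_patience` consecutive
#' epochs, and restores the best-validation-loss parameters. All randomness
#' (shuffling, augmentation) derives from `cfg$seed`, so equal seeds give
#' identical histories.
#'
#' @param model a `segmentation_model` (modified in place and returned).
#' @param cohort a `cohort` with non-empty train and validation splits.
#' @param cfg a [train_config].
#' @param verbose print a line per epoch.
#' @return list: `model`, `history` (data.frame of epoch, lr, train loss,
#'   validation loss and accuracy), `stop_reason`, `best_epoch`.
#' @export
train <- function(model, cohort, cfg = train_config(), verbose = FALSE) {
  tr <- cohort_split(cohort, "train")
  va <- cohort_split(cohort, "validation")
  if (length(tr) == 0 || length(va) == 0)
    stop("train: cohort must have non-empty train and validation splits")
  nc <- model$spec$n_classes
  weights <- if (is.null(cfg$class_weights)) rep(1, nc) else as.numeric(cfg$class_weights)
  if (length(weights) != nc) stop("train: class_weights length must equal n_classes")

  params <- mod_params(model)
  zero_grads(model)
  hist <- data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                     val_loss = numeric(), val_gacc = numeric())
  best <- Inf; best_epoch <- 0L; bad <- 0L
  best_snap <- snapshot_state(model)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch - 1L, cfg)
    ord <- with_seed(child_seed(cfg$seed, 7L, epoch), sample.int(length(tr)))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(tr), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(tr))]
      b <- with_seed(child_seed(cfg$seed, 11L, epoch * 1000L + start),
                     stack_images(tr[idx], augment = cfg$augment))
      scores <- nn_forward(model, b$pixels, training = TRUE)
      lg <- wce_loss_grad(scores, b$labels, weights)
      if (!is.finite(lg$loss))
        stop(sprintf("train: non-finite loss at epoch %d (diverged)", epoch))
      nn_backward(model, lg$grad)
      sgd_step(params, lr, cfg$momentum)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    finalize_bn_stats(model, stack_images(tr, augment = FALSE)$pixels)
    vs <- eval_split(model, va, weights)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / nb,
                                   val_loss = vs$loss, val_gacc = vs$gacc))
    if (verbose)
      message(sprintf("epoch %2d | lr %.2e | train %.4f | val %.4f | val gAcc %.4f",
                      epoch, lr, ep_loss / nb, vs$loss, vs$gacc))
    if (vs$loss < best) {
      best <- vs$loss; best_epoch <- epoch; bad <- 0L
      best_snap <- snapshot_state(model)
    } else {
      bad <- bad + 1L
      if (bad >= cfg$validation_patience) { stop_reason <- "patience"; break }
    }
  }
  restore_state(model, best_snap)
  list(model = model, history = hist, stop_reason = stop_reason,
       best_epoch = best_epoch)
}
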