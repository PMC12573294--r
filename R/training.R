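# Seeded minibatch training with a cosine-annealed learning rate,
# per-epoch validation, and best-validation checkpoint retention.

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T_max)) / 2`,
#' decaying from `lr_max` at `t = 0` to `lr_min` at `t = T_max` along a half
#' cosine.
#'
#' @param t Schedule position, `0 <= t <= T_max`.
#' @param T_max Schedule horizon.
#' @param lr_max,lr_min Endpoints, `lr_min < lr_max`.
#' @return The learning rate at `t`.
#' @export
cosine_lr <- function(t, T_max, lr_max = 0.02, lr_min = 1e-5) {
  if (any(t < 0) || any(t > T_max)) stop("t must lie in [0, T_max]")
  if (lr_min >= lr_max) stop("lr_min must be smaller than lr_max")
  lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T_max)) / 2
}

#' Training configuration
#'
#' Defaults follow the training protocol the model family was tuned under:
#' SGD with momentum 0.9 and weight decay 5e-4, batch size 32, cosine
#' annealing from 0.02 to 1e-5 over 100 epochs, softmax cross-entropy loss.
#'
#' @param epochs Number of epochs (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param momentum,weight_decay SGD hyperparameters; weight decay applies to
#'   convolution and linear weights only (not BN affines or biases).
#' @param lr_max,lr_min Learning-rate endpoints.
#' @param schedule `"cosine"` or `"fixed"` (constant at `lr_max`).
#' @param augment An [augment_config()] applied to training images, or
#'   `NULL` for none; validation is never augmented.
#' @param seed Integer seed governing shuffling, augmentation draws and any
#'   other randomness in the loop.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, momentum = 0.9,
                         weight_decay = 5e-4, lr_max = 0.02, lr_min = 1e-5,
                         schedule = c("cosine", "fixed"),
                         augment = augment_config(), seed = 1L) {
  schedule <- match.arg(schedule)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr_min >= lr_max) stop("lr_min must be smaller than lr_max")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 lr_max = lr_max, lr_min = lr_min, schedule = schedule,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

schedule_lr <- function(cfg, epoch) {
  if (cfg$schedule == "fixed") cfg$lr_max
  else cosine_lr(epoch - 1L, cfg$epochs, cfg$lr_max, cfg$lr_min)
}

sgd_step <- function(model, opt, lr, weight_decay, momentum) {
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0 && !is.null(dim(p$value)))
      g <- g + weight_decay * p$value
    v <- opt[[nm]]
    v <- if (is.null(v)) -lr * g else momentum * v - lr * g
    opt[[nm]] <- v
    p$value <- p$value + v
    p$grad <- NULL
  }
}

forward_eval_batches <- function(model, images, labels, stats, batch_size = 64L) {
  n <- length(images)
  pred <- integer(n)
  loss_sum <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    x <- normalize_tensor(images_to_tensor(images[idx]), stats)
    logits <- ag_no_grad(ag_value(model$forward(x, training = FALSE)))
    p <- softmax_rows(logits)
    pred[idx] <- apply(p, 1L, which.max)
    ii <- cbind(seq_along(idx), labels[idx])
    loss_sum <- loss_sum - sum(log(pmax(p[ii], 1e-300)))
  }
  list(loss = loss_sum / n, accuracy = mean(pred == labels), pred = pred)
}

#' Train a model on a split manifest
#'
#' Runs `cfg$epochs` epochs of minibatch softmax cross-entropy SGD over the
#' manifest's `train` split (with augmentation) and evaluates the `val`
#' split after each epoch (no augmentation, BN running statistics). Channel
#' normalization statistics are computed on the training split once and
#' attached to the model as `model$norm_stats`. The state with the best
#' validation accuracy is restored into the model when training ends.
#'
#' @param model An `rtcb_model` from [build_variant()].
#' @param manifest A manifest with assigned splits (see
#'   [stratified_split()]).
#' @param dir Directory the manifest image paths are relative to.
#' @param cfg A [train_config()].
#' @param checkpoint_path Optional path; when given, the best checkpoint is
#'   also written there via [save_checkpoint()].
#' @param verbose Print one line per epoch to stderr?
#' @return A list with `history` (data.frame: epoch, lr, train_loss,
#'   train_accuracy, val_loss, val_accuracy), `best` (epoch and
#'   val_accuracy), and the trained `model`.
#' @export
train_model <- function(model, manifest, dir, cfg = train_config(),
                        checkpoint_path = NULL, verbose = TRUE) {
  stopifnot(inherits(model, "rtcb_model"), inherits(cfg, "train_config"))
  tr <- manifest[manifest$split == "train", ]
  va <- manifest[manifest$split == "val", ]
  if (nrow(tr) == 0L) stop("training split is empty")
  if (nrow(va) == 0L) stop("validation split is empty")
  classes <- leaf_classes()
  trd <- load_images(tr, dir)
  vad <- load_images(va, dir)
  stats <- compute_norm_stats(trd$images)
  model$norm_stats <- stats
  if (is.null(model$spec$class_names)) model$spec$class_names <- classes

  opt <- new.env(parent = emptyenv())
  hist <- vector("list", cfg$epochs)
  best <- list(epoch = 0L, val_accuracy = -Inf, state = NULL)
  ntr <- nrow(tr)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- schedule_lr(cfg, epoch)
      perm <- sample.int(ntr)
      tl_sum <- 0; tn_correct <- 0L
      for (s in seq(1L, ntr, by = cfg$batch_size)) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, ntr)]
        imgs <- trd$images[idx]
        if (!is.null(cfg$augment))
          imgs <- lapply(imgs, augment, cfg = cfg$augment)
        x <- normalize_tensor(images_to_tensor(imgs), stats)
        y <- trd$labels[idx]
        logits <- model$forward(x, training = TRUE)
        loss <- ag_softmax_ce(logits, y)
        if (!is.finite(loss$value))
          stop(sprintf("non-finite loss at epoch %d (lr=%.4g); aborting", epoch, lr))
        ag_backward(loss)
        sgd_step(model, opt, lr, cfg$weight_decay, cfg$momentum)
        tl_sum <- tl_sum + loss$value * length(idx)
        tn_correct <- tn_correct +
          sum(apply(logits$value, 1L, which.max) == y)
      }
      ev <- forward_eval_batches(model, vad$images, vad$labels, stats)
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        train_loss = tl_sum / ntr, train_accuracy = tn_correct / ntr,
        val_loss = ev$loss, val_accuracy = ev$accuracy)
      if (ev$accuracy > best$val_accuracy) {
        best <- list(epoch = epoch, val_accuracy = ev$accuracy,
                     state = model_state(model))
      }
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.5f  train loss %.4f acc %.4f  val loss %.4f acc %.4f",
          epoch, lr, tl_sum / ntr, tn_correct / ntr, ev$loss, ev$accuracy))
    }
  })

  restore_state(model, best$state$state, best$state$bn)
  if (!is.null(checkpoint_path))
    save_checkpoint(model, checkpoint_path,
                    meta = list(best_epoch = best$epoch,
                                val_accuracy = best$val_accuracy,
                                seed = cfg$seed,
                                norm_stats = model$norm_stats))
  list(history = do.call(rbind, hist),
       best = best[c("epoch", "val_accuracy")],
       model = model)
}
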