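#' Fine-tuning configuration
#'
#' Defaults encode the reference recipe: 15 epochs, batch size 16, initial
#' learning rate 0.01 decayed by 0.1 after epochs 8 and 12, SGD momentum
#' 0.9, weight decay 1e-4, label smoothing 0.1, and random rotation as the
#' only augmentation.
#'
#' @param epochs,batch_size Training length and mini-batch size.
#' @param base_lr Initial learning rate.
#' @param lr_decay_epochs Epochs after which the rate is multiplied by
#'   `lr_decay_factor`.
#' @param lr_decay_factor Multiplicative decay.
#' @param sgd_momentum,weight_decay SGD hyperparameters.
#' @param label_smoothing Smoothing weight `sigma` in \[0, 1).
#' @param rotation_degrees Random-rotation bound (degrees).
#' @param freeze_trunk Train only the linear head.
#' @param seed Training seed.
#' @return A `supcam_finetune_config` list.
#' @export
finetune_config <- function(epochs = 15, batch_size = 16, base_lr = 0.01,
                            lr_decay_epochs = c(8, 12), lr_decay_factor = 0.1,
                            sgd_momentum = 0.9, weight_decay = 1e-4,
                            label_smoothing = 0.1, rotation_degrees = 180,
                            freeze_trunk = FALSE, seed = 1L) {
  stopifnot(epochs >= 0, batch_size > 0, base_lr > 0,
            label_smoothing >= 0, label_smoothing < 1)
  structure(as.list(environment()), class = "supcam_finetune_config")
}

#' Class-stratified train/validation/test split
#'
#' Within each class, `round(count * fraction)` samples (nearest integer) go
#' to the training and validation sets and the remainder to the test set,
#' so every split preserves the class proportions to within one sample.
#'
#' @param labels Character vector of class labels.
#' @param fractions Three non-negative fractions `(train, val, test)`
#'   summing to 1.
#' @return `list(train =, val =, test =)` of disjoint, exhaustive index
#'   vectors into `labels`.
#' @export
stratified_split <- function(labels, fractions = c(train = 0.6, val = 0.1, test = 0.3)) {
  if (!isTRUE(all.equal(sum(fractions), 1)) || any(fractions < 0)) {
    abort("fractions must be non-negative and sum to 1")
  }
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- floor(n * fractions[1] + 0.5)
    n_va <- min(floor(n * fractions[2] + 0.5), n - n_tr)
    train <- c(train, idx[seq_len(n_tr)])
    val <- c(val, idx[n_tr + seq_len(n_va)])
    test <- c(test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Label-smoothed target distribution
#'
#' The true class receives `(1 - sigma) + sigma / n_classes` and every other
#' class `sigma / n_classes`, so the vector sums to 1.
#'
#' @param true_class 1-based class index.
#' @param n_classes Number of classes (default 4).
#' @param sigma Smoothing weight in \[0, 1).
#' @return Probability vector of length `n_classes`.
#' @export
label_smoothing_targets <- function(true_class, n_classes = 4, sigma = 0.1) {
  if (sigma < 0 || sigma >= 1) abort("sigma must lie in [0, 1)")
  stopifnot(true_class >= 1, true_class <= n_classes)
  t <- rep(sigma / n_classes, n_classes)
  t[true_class] <- t[true_class] + 1 - sigma
  t
}

classifier_forward <- function(trunk, head, X) {
  H <- pmax(sweep(X %*% trunk$W1, 2, trunk$b1, `+`), 0)
  logits <- sweep(H %*% head$W, 2, head$b, `+`)
  m <- apply(logits, 1, max)
  P <- exp(logits - m)
  P <- P / rowSums(P)
  list(H = H, logits = logits, P = P)
}

#' Fine-tune a four-class linear classifier on trunk features
#'
#' Loads the pretrained trunk weights (the pooled hidden layer of the
#' encoder; the contrastive projection layer is discarded), attaches a
#' randomly initialized 4-way linear head, and trains with label-smoothed
#' cross-entropy under the stepped learning-rate schedule.  Random rotation
#' is the only augmentation.  The returned model carries the weights of the
#' epoch with the best validation accuracy.
#'
#' @param pretrained A `supcam_pretrain` fit, a checkpoint path saved with
#'   [save_checkpoint()], or `NULL` to train from random initialization.
#' @param samples List of [labeled_sample()] objects.
#' @param split A [stratified_split()] list with `train` and `val` indices.
#' @param config A [finetune_config()].
#' @param pool_grid,hidden Backbone shape; only used when `pretrained` is
#'   `NULL`.
#' @return A `supcam_classifier` with trunk, head, class order, training
#'   `log` tibble and `best_epoch`.
#' @export
finetune_run <- function(pretrained, samples, split, config = finetune_config(),
                         pool_grid = 8, hidden = 48) {
  set.seed(config$seed)
  canvas <- nrow(samples[[1]]$image)
  if (inherits(pretrained, "character")) {
    pretrained <- load_checkpoint(pretrained, expect_architecture = "pooled_mlp")$fit
  }
  if (inherits(pretrained, "supcam_pretrain")) {
    enc <- pretrained$encoder
    if (enc$canvas_size != canvas) {
      abort(sprintf("pretrained trunk expects %dx%d images, got %dx%d",
                    enc$canvas_size, enc$canvas_size, canvas, canvas))
    }
    trunk <- list(W1 = enc$params$W1, b1 = enc$params$b1)
    pool_grid <- enc$pool_grid; hidden <- enc$hidden
  } else if (is.null(pretrained)) {
    enc <- encoder_init(canvas, pool_grid, hidden)
    trunk <- list(W1 = enc$params$W1, b1 = enc$params$b1)
  } else {
    abort("`pretrained` must be a supcam_pretrain fit, a checkpoint path, or NULL")
  }
  classes <- cluster_labels()
  head <- list(W = matrix(rnorm(hidden * 4, sd = sqrt(1 / hidden)), hidden, 4),
               b = numeric(4))

  train_idx <- split$train; val_idx <- split$val
  y_train <- match(vapply(samples[train_idx], `[[`, character(1), "label"), classes)
  Targets <- t(vapply(y_train, label_smoothing_targets,
                      numeric(4), n_classes = 4, sigma = config$label_smoothing))
  X_val <- pool_images(lapply(samples[val_idx], `[[`, "image"), canvas, pool_grid)
  y_val <- match(vapply(samples[val_idx], `[[`, character(1), "label"), classes)

  params <- c(trunk, head)
  opt <- sgd_state_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- config$base_lr * config$lr_decay_factor^sum(epoch > config$lr_decay_epochs)
    order <- sample.int(length(train_idx))
    ep_loss <- numeric(0)
    for (b in seq(1L, length(order), by = config$batch_size)) {
      sel <- order[b:min(b + config$batch_size - 1L, length(order))]
      imgs <- lapply(samples[train_idx[sel]], function(s) {
        random_rotation(s$image, config$rotation_degrees)
      })
      X <- pool_images(imgs, canvas, pool_grid)
      Tb <- Targets[sel, , drop = FALSE]
      trunk <- params[c("W1", "b1")]; head <- params[c("W", "b")]
      fwd <- classifier_forward(trunk, head, X)
      loss <- -mean(rowSums(Tb * log(pmax(fwd$P, 1e-12))))
      dlogits <- (fwd$P - Tb) / nrow(X)
      grads <- list(W = t(fwd$H) %*% dlogits, b = colSums(dlogits))
      if (!config$freeze_trunk) {
        dH <- (dlogits %*% t(head$W)) * (fwd$H > 0)
        grads$W1 <- t(X) %*% dH
        grads$b1 <- colSums(dH)
      } else {
        grads$W1 <- trunk$W1 * 0
        grads$b1 <- trunk$b1 * 0
      }
      upd <- sgd_update(params, grads[names(params)], opt, lr,
                        config$sgd_momentum, config$weight_decay)
      params <- upd$params; opt <- upd$state
      ep_loss <- c(ep_loss, loss)
    }
    val_acc <- if (length(val_idx)) {
      fwd <- classifier_forward(params[c("W1", "b1")], params[c("W", "b")], X_val)
      mean(max.col(fwd$P) == y_val)
    } else NA_real_
    if (!is.na(val_acc) && val_acc > best$acc) {
      best <- list(acc = val_acc, params = params, epoch = epoch)
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = mean(ep_loss),
                                   val_accuracy = val_acc, lr = lr)
  }
  final <- if (is.finite(best$acc)) best$params else params
  structure(list(
    trunk = final[c("W1", "b1")], head = final[c("W", "b")],
    classes = classes, canvas_size = canvas, pool_grid = pool_grid,
    hidden = hidden, config = config,
    log = dplyr::bind_rows(log),
    best_epoch = if (is.finite(best$acc)) best$epoch else NA_integer_,
    architecture = "pooled_mlp"
  ), class = "supcam_classifier")
}

#' Predict cluster types
#'
#' @param object A `supcam_classifier`.
#' @param newdata List of [labeled_sample()] objects or image matrices.
#' @param ... Unused.
#' @return Tibble with the predicted class and per-class probabilities.
#' @export
predict.supcam_classifier <- function(object, newdata, ...) {
  imgs <- lapply(newdata, function(s) if (is_labeled_sample(s)) s$image else s)
  X <- pool_images(imgs, object$canvas_size, object$pool_grid)
  fwd <- classifier_forward(object$trunk, object$head, X)
  probs <- tibble::as_tibble(fwd$P, .name_repair = ~ paste0(".prob_", object$classes))
  dplyr::bind_cols(
    tibble::tibble(.pred_class = object$classes[max.col(fwd$P)]),
    probs
  )
}

#' @export
print.supcam_classifier <- function(x, ...) {
  cat(sprintf("<supcam_classifier> %d classes, trunk %d features, best epoch %s\n",
              length(x$classes), x$hidden, x$best_epoch))
  invisible(x)
}

#' Evaluate a classifier on labeled samples
#'
#' @param model A `supcam_classifier`.
#' @param samples List of [labeled_sample()] objects.
#' @return A `supcam_metrics` object from [confusion_and_metrics()].
#' @export
evaluate_classifier <- function(model, samples) {
  truth <- vapply(samples, `[[`, character(1), "label")
  pred <- predict(model, samples)$.pred_class
  confusion_and_metrics(truth, pred, classes = model$classes)
}
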