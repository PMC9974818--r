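#' Pretraining configuration
#'
#' Defaults encode the reference recipe: 128-d embeddings, temperature
#' 0.07, angular margin 0.2, queue capacity 1024, batch size 32, 200 epochs
#' with 20 linear warm-up epochs to a base learning rate of 0.03 followed by
#' cosine annealing, SGD momentum 0.9 and weight decay 1e-4.  The
#' category-invariant augmentations are random resized crop and horizontal
#' flip.
#'
#' @param embed_dim Embedding dimension.
#' @param temperature Contrastive softmax temperature.
#' @param margin Additive angular margin of the self-margin term.
#' @param queue_capacity Memory-queue capacity.
#' @param batch_size Mini-batch size.
#' @param epochs,warmup_epochs Training length and linear warm-up length.
#' @param base_lr Peak learning rate reached after warm-up.
#' @param sgd_momentum,weight_decay SGD hyperparameters.
#' @param encoder_momentum Key-encoder moving-average coefficient.
#' @param crop_scale Area-fraction bounds of the random resized crop.
#' @param margin_mode `"self"` (default), `"parametric"`, `"cluster"` or
#'   `"none"` — which angular-margin head accompanies the SupCon term.
#' @param cluster_center_momentum Moving average for cluster-margin centers.
#' @param pool_grid,hidden Backbone shape (see [encoder_init()]).
#' @param seed Training seed.
#' @return A `supcam_pretrain_config` list.
#' @export
pretrain_config <- function(embed_dim = 128, temperature = 0.07, margin = 0.2,
                            queue_capacity = 1024, batch_size = 32,
                            epochs = 200, warmup_epochs = 20, base_lr = 0.03,
                            sgd_momentum = 0.9, weight_decay = 1e-4,
                            encoder_momentum = 0.999,
                            crop_scale = c(0.2, 1),
                            margin_mode = c("self", "parametric", "cluster", "none"),
                            cluster_center_momentum = 0.9,
                            pool_grid = 8, hidden = 48, seed = 1L) {
  margin_mode <- match.arg(margin_mode)
  stopifnot(embed_dim > 0, temperature > 0, margin >= 0, queue_capacity > 0,
            batch_size > 0, epochs >= 0, warmup_epochs >= 0, base_lr > 0,
            encoder_momentum >= 0, encoder_momentum < 1)
  structure(as.list(environment()), class = "supcam_pretrain_config")
}

# learning rate at 1-based epoch e: linear warm-up then cosine annealing
pretrain_lr <- function(config, epoch) {
  if (epoch <= config$warmup_epochs) {
    return(config$base_lr * epoch / max(1, config$warmup_epochs))
  }
  after <- config$epochs - config$warmup_epochs
  frac <- if (after <= 0) 0 else (epoch - config$warmup_epochs) / after
  config$base_lr * 0.5 * (1 + cos(pi * frac))
}

#' Initialize pretraining state
#'
#' Builds the query/key encoder pair (the key encoder starts as an exact
#' copy), the sentinel-initialized memory queue, the optimizer state and —
#' for the parametric-margin variant — the trainable class-weight matrix.
#'
#' @param config A [pretrain_config()].
#' @param canvas_size Image side in pixels.
#' @return A `supcam_pretrain_state` list.
#' @export
pretrain_state_init <- function(config, canvas_size) {
  f_q <- encoder_init(canvas_size, config$pool_grid, config$hidden, config$embed_dim)
  f_k <- f_q
  W <- NULL
  if (config$margin_mode == "parametric") {
    W <- matrix(rnorm(4 * config$embed_dim), 4, config$embed_dim)
    W <- W / sqrt(rowSums(W^2))
  }
  structure(list(
    f_q = f_q, f_k = f_k,
    queue = memory_queue(config$queue_capacity, config$embed_dim),
    opt = sgd_state_init(f_q$params),
    class_weights = W,
    class_weight_opt = if (is.null(W)) NULL else list(v = W * 0),
    centers = NULL,
    config = config
  ), class = "supcam_pretrain_state")
}

# gradient of the additive-angular-margin loss w.r.t. the raw class weights
aam_grad_weights <- function(q, W, true_index, params) {
  qh <- q / sqrt(sum(q^2))
  Wh <- W / sqrt(rowSums(W^2))
  tau <- params$temperature
  s <- pmin(pmax(as.vector(Wh %*% qh), -1 + .COS_EPS), 1 - .COS_EPS)
  theta_p <- acos(s[true_index])
  logits <- s / tau
  logits[true_index] <- cos(theta_p + params$margin) / tau
  p <- exp(logits - logsumexp(logits))
  coeff <- p / tau
  coeff[true_index] <- (p[true_index] - 1) / tau *
    (sin(theta_p + params$margin) / sin(theta_p))
  g <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(nrow(W))) {
    g[j, ] <- coeff[j] * project_grad(W[j, ], qh)
  }
  g
}

#' One pretraining step
#'
#' For every `(primary, candidate)` pair: the primary image is augmented
#' twice into the query and key views; the candidate is combined with the
#' primary by category-variant composition and augmented into the third
#' view; the three views are encoded (queries by the trainable encoder,
#' keys by the momentum encoder, without gradient tracking); keys are
#' partitioned against the queue by label; the loss is the SupCon term over
#' all positives plus the configured margin term (self-margin on the
#' intrinsic key only, by default).  One SGD step updates the query
#' encoder, the key encoder takes a momentum update, and all `(k_plus, y_p)`
#' and `(k_g, y_g)` keys are pushed into the queue.
#'
#' @param pairs List of `list(primary =, candidate =)` [labeled_sample()]
#'   pairs.
#' @param state A [pretrain_state_init()] state.
#' @param composition A [composition_config()].
#' @param lr Learning rate for this step.
#' @return `list(loss =, state =)` — mean total loss over the batch and the
#'   updated state.
#' @export
pretrain_step <- function(pairs, state, composition = composition_config(), lr = 0.03) {
  cfg <- state$config
  n <- length(pairs)
  params <- loss_params(cfg$temperature, cfg$margin)

  x_q <- vector("list", n); x_k <- vector("list", n); x_g <- vector("list", n)
  y_p <- character(n); y_g <- character(n)
  for (i in seq_len(n)) {
    pr <- pairs[[i]]$primary; cd <- pairs[[i]]$candidate
    x_q[[i]] <- augment_pretrain_view(pr$image, cfg$crop_scale)
    x_k[[i]] <- augment_pretrain_view(pr$image, cfg$crop_scale)
    g <- compose_pair(pr, cd, composition)
    x_g[[i]] <- augment_pretrain_view(g$image, cfg$crop_scale)
    y_p[i] <- pr$label
    y_g[i] <- g$label
  }

  fwd_q <- encoder_forward(state$f_q, x_q, cache = TRUE)
  keys <- encoder_forward(state$f_k, c(x_k, x_g))$Q  # no gradients through keys
  K_plus <- keys[seq_len(n), , drop = FALSE]
  K_g <- keys[n + seq_len(n), , drop = FALSE]

  if (cfg$margin_mode == "cluster") {
    state$centers <- cluster_margin_centers(state$queue, state$centers,
                                            cfg$cluster_center_momentum)
  }

  dQ <- matrix(0, n, cfg$embed_dim)
  dW_cls <- if (!is.null(state$class_weights)) state$class_weights * 0 else NULL
  losses <- numeric(n)
  for (i in seq_len(n)) {
    q <- fwd_q$Q[i, ]
    part <- partition_keys(y_p[i], state$queue,
                           rbind(K_plus[i, ], K_g[i, ]),
                           c(y_p[i], y_g[i]))
    if (nrow(part$negatives) == 0L) { losses[i] <- NA_real_; next }
    sc <- supcon_loss(q, part$positives, part$negatives, cfg$temperature, grad = TRUE)
    g_i <- sc$grad_q
    margin_value <- 0
    if (cfg$margin_mode == "self") {
      sm <- self_margin_loss(q, K_plus[i, ], part$negatives, params, grad = TRUE)
      margin_value <- sm$value
      g_i <- g_i + sm$grad_q
    } else if (cfg$margin_mode == "parametric") {
      idx <- match(y_p[i], cluster_labels())
      am <- additive_angular_margin_loss(q, state$class_weights, idx, params, grad = TRUE)
      margin_value <- am$value
      g_i <- g_i + am$grad_q
      dW_cls <- dW_cls + aam_grad_weights(q, state$class_weights, idx, params)
    } else if (cfg$margin_mode == "cluster") {
      idx <- match(y_p[i], cluster_labels())
      if (all(is.finite(state$centers))) {
        am <- additive_angular_margin_loss(q, state$centers, idx, params, grad = TRUE)
        margin_value <- am$value
        g_i <- g_i + am$grad_q
      }
    }
    losses[i] <- total_pretrain_loss(sc$value, margin_value)
    dQ[i, ] <- g_i
  }
  n_eff <- sum(!is.na(losses))
  if (n_eff > 0) {
    grads <- encoder_backward(state$f_q, fwd_q, dQ / n_eff)
    upd <- sgd_update(state$f_q$params, grads, state$opt, lr,
                      cfg$sgd_momentum, cfg$weight_decay)
    state$f_q$params <- upd$params
    state$opt <- upd$state
    if (!is.null(dW_cls)) {
      state$class_weight_opt$v <- cfg$sgd_momentum * state$class_weight_opt$v + dW_cls / n_eff
      state$class_weights <- state$class_weights - lr * state$class_weight_opt$v
    }
  }
  state$f_k <- momentum_update(state$f_k, state$f_q, cfg$encoder_momentum)
  state$queue <- queue_push(state$queue, rbind(K_plus, K_g), c(y_p, y_g))
  list(loss = mean(losses, na.rm = TRUE), state = state)
}

#' Supervised contrastive pretraining
#'
#' Runs the full pretraining loop over labeled samples: each epoch shuffles
#' the data into primary/candidate pairs (candidates drawn at random),
#' applies [pretrain_step()] per batch under the warm-up + cosine learning
#' rate schedule, and records the mean epoch loss.
#'
#' @param samples List of [labeled_sample()] objects (or a manifest tibble,
#'   which is loaded via [load_samples()]).
#' @param config A [pretrain_config()].
#' @param composition A [composition_config()].
#' @param verbose Print per-epoch loss lines.
#' @return A `supcam_pretrain` fit: the trained encoder, the final state,
#'   the config and a `log` tibble with `epoch`, `loss`, `lr`.
#' @export
supcam_pretrain <- function(samples, config = pretrain_config(),
                            composition = composition_config(), verbose = FALSE) {
  if (is.data.frame(samples)) samples <- load_samples(samples)
  stopifnot(length(samples) >= 2)
  set.seed(config$seed)
  canvas <- nrow(samples[[1]]$image)
  state <- pretrain_state_init(config, canvas)
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- pretrain_lr(config, epoch)
    order <- sample.int(length(samples))
    batch_starts <- seq(1L, length(order), by = config$batch_size)
    losses <- numeric(0)
    for (b in batch_starts) {
      idx <- order[b:min(b + config$batch_size - 1L, length(order))]
      cand <- sample.int(length(samples), length(idx), replace = TRUE)
      pairs <- purrr::map2(idx, cand, function(i, j) {
        list(primary = samples[[i]], candidate = samples[[j]])
      })
      step <- pretrain_step(pairs, state, composition, lr)
      state <- step$state
      losses <- c(losses, step$loss)
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses), lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.5f", epoch, mean(losses), lr))
    }
  }
  structure(list(encoder = state$f_q, state = state, config = config,
                 composition = composition,
                 log = dplyr::bind_rows(log)),
            class = "supcam_pretrain")
}

#' Save a pretraining fit as a checkpoint
#'
#' Stores the trunk weights together with the configuration and seed so the
#' fit can be reloaded (and fine-tuned) later via [load_checkpoint()] or
#' directly by [finetune_run()].
#'
#' @param fit A `supcam_pretrain` object.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_pretrain_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "supcam_pretrain"))
  save_checkpoint(list(architecture = fit$encoder$architecture,
                       params = fit$encoder$params,
                       config = fit$config, seed = fit$config$seed,
                       fit = fit), path)
}

#' @export
print.supcam_pretrain <- function(x, ...) {
  cat(sprintf("<supcam_pretrain> %d epochs, final loss %.4f, margin mode %s\n",
              nrow(x$log), utils::tail(x$log$loss, 1), x$config$margin_mode))
  invisible(x)
}
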