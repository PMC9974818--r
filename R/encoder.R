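# Compact trainable encoder: block-mean pooling of the image to a coarse
# grid, a hidden fully connected ReLU layer (the "trunk"), and a linear
# projection to the embedding space.  Forward and backward passes are
# written out explicitly; parameters live in a plain named list so the
# momentum (key) encoder is a structural copy updated without gradients.

#' Initialize an encoder
#'
#' The desk-scale backbone: images are block-mean pooled to a
#' `pool_grid x pool_grid` grid, passed through one fully connected ReLU
#' layer of `hidden` units (the trunk features reused at fine-tuning) and
#' projected linearly to `embed_dim` dimensions; embeddings are
#' unit-normalized by the caller.  The architecture is pluggable through
#' this constructor: any encoder exposing the same forward/backward
#' contract can stand in for full-scale backbones.
#'
#' @param canvas_size Input image side in pixels.
#' @param pool_grid Pooled grid side (default 8, i.e. 64 pooled features).
#' @param hidden Trunk width (default 48).
#' @param embed_dim Embedding dimension (default 128).
#' @return A `supcam_encoder` list of parameters and shape metadata.
#' @export
encoder_init <- function(canvas_size, pool_grid = 8, hidden = 48, embed_dim = 128) {
  n_in <- pool_grid^2
  he <- function(fan_in, n) matrix(rnorm(n * fan_in, sd = sqrt(2 / fan_in)), fan_in, n)
  structure(list(
    architecture = "pooled_mlp",
    canvas_size = as.integer(canvas_size),
    pool_grid = as.integer(pool_grid),
    hidden = as.integer(hidden),
    embed_dim = as.integer(embed_dim),
    params = list(W1 = he(n_in, hidden), b1 = numeric(hidden),
                  W2 = he(hidden, embed_dim),
                  b2 = rnorm(embed_dim, sd = 1e-3))  # keeps embeddings off exact zero
  ), class = "supcam_encoder")
}

# images: list of matrices -> n x pool_grid^2 matrix of block means
pool_images <- function(images, canvas_size, pool_grid) {
  breaks <- pmin(ceiling(seq_len(canvas_size) / (canvas_size / pool_grid)), pool_grid)
  cnt <- tabulate(breaks, pool_grid)
  t(vapply(images, function(img) {
    stopifnot(nrow(img) == canvas_size, ncol(img) == canvas_size)
    s <- rowsum(t(rowsum(img, breaks)), breaks)  # s[j, i]: col block j, row block i
    as.vector(t(s) / outer(cnt, cnt))
  }, numeric(pool_grid^2))) / 255
}

#' Encode a batch of images
#'
#' @param encoder A [encoder_init()] object.
#' @param images List of image matrices.
#' @param cache Keep intermediate activations for [encoder_backward()].
#' @return List with `Q` (n x d unit-row embedding matrix), `H` (trunk
#'   features) and, when `cache = TRUE`, the pooled inputs.
#' @export
encoder_forward <- function(encoder, images, cache = FALSE) {
  X <- pool_encoder_input(encoder, images)
  p <- encoder$params
  H <- pmax(sweep(X %*% p$W1, 2, p$b1, `+`), 0)
  Z <- sweep(H %*% p$W2, 2, p$b2, `+`)
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- 1
  Q <- Z / nrm
  out <- list(Q = Q, H = H)
  if (cache) { out$X <- X; out$Z <- Z; out$norm <- nrm }
  out
}

pool_encoder_input <- function(encoder, images) {
  pool_images(images, encoder$canvas_size, encoder$pool_grid)
}

#' Backpropagate through an encoder
#'
#' @param encoder A [encoder_init()] object.
#' @param fwd Forward pass from [encoder_forward()] with `cache = TRUE`.
#' @param dQ Gradient of the loss w.r.t. the unit-normalized embeddings.
#' @return Named list of parameter gradients matching `encoder$params`.
#' @export
encoder_backward <- function(encoder, fwd, dQ) {
  # through row normalization: dZ = (dQ - Q * rowSums(dQ * Q)) / ||Z||
  dZ <- (dQ - fwd$Q * rowSums(dQ * fwd$Q)) / fwd$norm
  p <- encoder$params
  dH <- (dZ %*% t(p$W2)) * (fwd$H > 0)
  list(W1 = t(fwd$X) %*% dH, b1 = colSums(dH),
       W2 = t(fwd$H) %*% dZ, b2 = colSums(dZ))
}

#' Momentum update of the key encoder
#'
#' Every key-encoder parameter is replaced by
#' `mu * theta_k + (1 - mu) * theta_q`; the key encoder is never updated by
#' gradients.
#'
#' @param f_k,f_q Key and query encoders with matching parameter shapes.
#' @param mu Momentum coefficient in \[0, 1\].
#' @return The updated key encoder.
#' @export
momentum_update <- function(f_k, f_q, mu) {
  stopifnot(mu >= 0, mu <= 1)
  for (nm in names(f_q$params)) {
    if (!all(dim_or_len(f_k$params[[nm]]) == dim_or_len(f_q$params[[nm]]))) {
      abort(sprintf("parameter shape mismatch for \"%s\"", nm))
    }
    f_k$params[[nm]] <- mu * f_k$params[[nm]] + (1 - mu) * f_q$params[[nm]]
  }
  f_k
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# SGD with momentum and decoupled-from-schedule weight decay, the reference
# optimizer for both training steps.
sgd_state_init <- function(params) lapply(params, function(p) p * 0)

sgd_update <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state[[nm]] <- momentum * state[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * state[[nm]]
  }
  list(params = params, state = state)
}
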