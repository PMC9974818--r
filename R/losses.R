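#' Contrastive loss parameters
#'
#' @param temperature Softmax temperature `tau` > 0 (default 0.07).
#' @param margin Additive angular margin `m` in \[0, pi) radians
#'   (default 0.2).
#' @return A `supcam_loss_params` list.
#' @export
loss_params <- function(temperature = 0.07, margin = 0.2) {
  stopifnot(temperature > 0, margin >= 0, margin < pi)
  structure(list(temperature = temperature, margin = margin),
            class = "supcam_loss_params")
}

# inner-product clamp keeping arccos (and the margin-path gradient) finite
# at angles 0 and pi
.COS_EPS <- 1e-7

unit_rows <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) abort("zero-norm embedding")
  x / nrm
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# backpropagate dL/d(q_hat) to dL/dq through q_hat = q / ||q||
project_grad <- function(q, g) {
  nrm <- sqrt(sum(q^2))
  qh <- q / nrm
  (g - qh * sum(qh * g)) / nrm
}

#' Angle between two embeddings
#'
#' Arccosine of the inner product of the unit-normalized vectors, with the
#' product clamped to `[-1 + 1e-7, 1 - 1e-7]` before `acos` so gradients
#' through the margin path stay finite at 0 and pi.
#'
#' @param q,k Numeric vectors (nonzero norm).
#' @return Angle in radians, in \[0, pi\].
#' @export
cosine_angle <- function(q, k) {
  qn <- sqrt(sum(q^2)); kn <- sqrt(sum(k^2))
  if (qn == 0 || kn == 0) abort("zero-norm embedding")
  acos(min(max(sum(q * k) / (qn * kn), -1 + .COS_EPS), 1 - .COS_EPS))
}

#' InfoNCE loss
#'
#' `-log( exp(q.k_p / tau) / (exp(q.k_p / tau) + sum_i exp(q.k_i / tau)) )`
#' for a single positive key and a set of negatives, computed with
#' log-sum-exp stabilization.  Inputs are unit-normalized internally, so
#' inner products are cosines.
#'
#' @param q Query embedding.
#' @param k_pos Positive key.
#' @param negatives Negative keys: a matrix (rows = keys) or list of vectors;
#'   must be non-empty.
#' @param temperature Softmax temperature.
#' @param grad If `TRUE`, also return the analytic gradient with respect to
#'   the raw (pre-normalization) query.
#' @return The loss value, or `list(value, grad_q)` when `grad = TRUE`.
#' @export
info_nce_loss <- function(q, k_pos, negatives, temperature = 0.07, grad = FALSE) {
  K <- unit_rows(negatives)
  if (nrow(K) < 1L) abort("at least one negative key is required")
  qh <- unit_rows(q)[1L, ]
  kp <- unit_rows(k_pos)[1L, ]
  s_pos <- sum(qh * kp)
  s_neg <- as.vector(K %*% qh)
  z <- c(s_pos, s_neg) / temperature
  value <- -z[1L] + logsumexp(z)
  if (!grad) return(value)
  p <- exp(z - logsumexp(z))
  g_hat <- ((p[1L] - 1) * kp + colSums(K * p[-1L])) / temperature
  list(value = value, grad_q = project_grad(q, g_hat))
}

#' Supervised contrastive (SupCon) loss
#'
#' Average over the positive set of per-positive InfoNCE terms in which the
#' denominator contains only that positive plus the negatives (other
#' positives never enter the denominator).  With a single positive this is
#' exactly [info_nce_loss()].
#'
#' @param q Query embedding.
#' @param positives Positive keys (matrix or list; non-empty).
#' @inheritParams info_nce_loss
#' @return The loss value, or `list(value, grad_q)` when `grad = TRUE`.
#' @export
supcon_loss <- function(q, positives, negatives, temperature = 0.07, grad = FALSE) {
  P <- unit_rows(positives)
  K <- unit_rows(negatives)
  if (nrow(P) < 1L) abort("at least one positive key is required")
  if (nrow(K) < 1L) abort("at least one negative key is required")
  qh <- unit_rows(q)[1L, ]
  z_pos <- as.vector(P %*% qh) / temperature
  z_neg <- as.vector(K %*% qh) / temperature
  m <- max(z_pos, z_neg)
  e_neg <- exp(z_neg - m)
  s_neg <- sum(e_neg)
  denom <- exp(z_pos - m) + s_neg
  value <- mean(-(z_pos - m) + log(denom))
  if (!grad) return(value)
  np <- nrow(P)
  p_pos <- exp(z_pos - m) / denom
  g_pos <- (p_pos - 1) / (np * temperature)
  g_neg <- e_neg * sum(1 / denom) / (np * temperature)
  g_hat <- as.vector(t(P) %*% g_pos + t(K) %*% g_neg)
  list(value = value, grad_q = project_grad(q, g_hat))
}

#' Self-margin loss
#'
#' InfoNCE with an additive angular margin applied only to the intrinsic
#' positive pair `(q, k_plus)`:
#' `-log( exp(cos(theta + m)/tau) / (exp(cos(theta + m)/tau) +
#' sum_i exp(cos(theta_i)/tau)) )` where `theta` is the angle between `q`
#' and `k_plus`.  No other positive receives a margin or appears in the
#' denominator.  With `m = 0` this reduces exactly to [info_nce_loss()].
#'
#' @param q Query embedding.
#' @param k_plus The intrinsic positive key (second view of the query image).
#' @param negatives Negative keys (matrix or list; non-empty).
#' @param params A [loss_params()] carrying `temperature` and `margin`.
#' @param grad If `TRUE`, also return the analytic gradient w.r.t. raw `q`.
#' @return The loss value, or `list(value, grad_q)` when `grad = TRUE`.
#' @export
self_margin_loss <- function(q, k_plus, negatives, params = loss_params(), grad = FALSE) {
  K <- unit_rows(negatives)
  if (nrow(K) < 1L) abort("at least one negative key is required")
  qh <- unit_rows(q)[1L, ]
  kp <- unit_rows(k_plus)[1L, ]
  tau <- params$temperature
  cth <- min(max(sum(qh * kp), -1 + .COS_EPS), 1 - .COS_EPS)
  theta <- acos(cth)
  a <- cos(theta + params$margin)
  s_neg <- as.vector(K %*% qh)
  z <- c(a, s_neg) / tau
  value <- -z[1L] + logsumexp(z)
  if (!grad) return(value)
  p <- exp(z - logsumexp(z))
  # d a / d cos(theta) = sin(theta + m) / sin(theta)
  dadc <- sin(theta + params$margin) / sin(theta)
  g_hat <- ((p[1L] - 1) * dadc * kp + colSums(K * p[-1L])) / tau
  list(value = value, grad_q = project_grad(q, g_hat))
}

#' Additive angular margin (ArcFace-style) loss
#'
#' Softmax cross-entropy over class-weight angles with the margin added to
#' the true-class angle only; used by the parametric- and cluster-margin
#' pretraining variants.
#'
#' @param q Query embedding.
#' @param class_weights Class center vectors (matrix rows or list), unit
#'   normalized internally.
#' @param true_index Index (1-based) of the true class in `class_weights`.
#' @param params A [loss_params()].
#' @param grad If `TRUE`, also return the analytic gradient w.r.t. raw `q`.
#' @return The loss value, or `list(value, grad_q)` when `grad = TRUE`.
#' @export
additive_angular_margin_loss <- function(q, class_weights, true_index,
                                         params = loss_params(), grad = FALSE) {
  W <- unit_rows(class_weights)
  if (!(true_index >= 1 && true_index <= nrow(W))) {
    abort(sprintf("true_index %s out of range 1..%d", true_index, nrow(W)))
  }
  qh <- unit_rows(q)[1L, ]
  tau <- params$temperature
  s <- pmin(pmax(as.vector(W %*% qh), -1 + .COS_EPS), 1 - .COS_EPS)
  theta_p <- acos(s[true_index])
  logits <- s / tau
  logits[true_index] <- cos(theta_p + params$margin) / tau
  value <- -logits[true_index] + logsumexp(logits)
  if (!grad) return(value)
  p <- exp(logits - logsumexp(logits))
  coeff <- p / tau
  coeff[true_index] <- (p[true_index] - 1) / tau *
    (sin(theta_p + params$margin) / sin(theta_p))
  g_hat <- colSums(W * coeff)
  list(value = value, grad_q = project_grad(q, g_hat))
}

#' Total pretraining loss
#'
#' The pretraining objective is the sum of the SupCon term and the
#' self-margin term.
#'
#' @param supcon_value,self_margin_value Finite loss components.
#' @return Their sum.
#' @export
total_pretrain_loss <- function(supcon_value, self_margin_value) {
  if (!is.finite(supcon_value) || !is.finite(self_margin_value)) {
    abort("loss components must be finite")
  }
  supcon_value + self_margin_value
}
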