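#' Labeled FIFO memory queue
#'
#' Fixed-capacity queue of `(embedding, label)` key pairs ordered oldest to
#' newest; pushes evict strictly oldest-first.  At construction the queue is
#' filled with random unit vectors carrying a sentinel label that never
#' matches a real class, so the initial contents act as pure negatives until
#' evicted.
#'
#' @param capacity Maximum number of stored keys (default 1024).
#' @param embed_dim Embedding dimension (default 128).
#' @param init `"random"` (sentinel-labeled random unit keys, full queue) or
#'   `"empty"`.
#' @return A `supcam_queue` with fields `embeddings` (size x d matrix,
#'   oldest first), `labels` and `capacity`.
#' @export
memory_queue <- function(capacity = 1024, embed_dim = 128,
                         init = c("random", "empty")) {
  init <- match.arg(init)
  stopifnot(capacity >= 1)
  if (init == "random") {
    E <- matrix(rnorm(capacity * embed_dim), capacity, embed_dim)
    E <- E / sqrt(rowSums(E^2))
    labels <- rep(queue_sentinel_label(), capacity)
  } else {
    E <- matrix(numeric(0), 0, embed_dim)
    labels <- character(0)
  }
  structure(list(embeddings = E, labels = labels,
                 capacity = as.integer(capacity)),
            class = "supcam_queue")
}

#' @rdname memory_queue
#' @export
queue_sentinel_label <- function() "__queue_init__"

#' @rdname memory_queue
#' @param queue A `supcam_queue`.
#' @export
queue_size <- function(queue) nrow(queue$embeddings)

#' Push keys into the queue (FIFO)
#'
#' Appends `(embedding, label)` pairs in order, evicting the oldest entries
#' once capacity is exceeded.
#'
#' @param queue A [memory_queue()].
#' @param embeddings Matrix of key embeddings (rows) or a single vector.
#' @param labels Character vector, one label per pushed key.
#' @return The updated queue.
#' @export
queue_push <- function(queue, embeddings, labels) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  stopifnot(nrow(embeddings) == length(labels))
  if (nrow(embeddings) > queue$capacity) {
    abort(sprintf("cannot push %d keys into a queue of capacity %d",
                  nrow(embeddings), queue$capacity))
  }
  E <- rbind(queue$embeddings, embeddings)
  L <- c(queue$labels, labels)
  excess <- nrow(E) - queue$capacity
  if (excess > 0) {
    E <- E[-seq_len(excess), , drop = FALSE]
    L <- L[-seq_len(excess)]
  }
  queue$embeddings <- E
  queue$labels <- L
  queue
}

#' Partition keys into positives and negatives for a query
#'
#' Pools the queue contents with the current extra keys (the intrinsic key
#' `k_plus` and the composed key `k_g`) and splits them by label match with
#' the query: keys sharing the query's class are positives, all others —
#' including sentinel-labeled initial keys — are negatives.
#'
#' @param q_label The query's class label.
#' @param queue A [memory_queue()].
#' @param extra_embeddings Matrix (rows) or vector of current-batch keys.
#' @param extra_labels Labels of the extra keys.
#' @return List with `positives` and `negatives` embedding matrices and the
#'   corresponding label vectors.
#' @export
partition_keys <- function(q_label, queue, extra_embeddings = NULL, extra_labels = character(0)) {
  assert_label(q_label, arg = "q_label")
  if (!is.null(extra_embeddings) && is.null(dim(extra_embeddings))) {
    extra_embeddings <- matrix(extra_embeddings, nrow = 1L)
  }
  E <- rbind(queue$embeddings, extra_embeddings)
  L <- c(queue$labels, extra_labels)
  pos <- L == q_label
  list(positives = E[pos, , drop = FALSE],
       negatives = E[!pos, , drop = FALSE],
       positive_labels = L[pos],
       negative_labels = L[!pos])
}

#' Moving-average class centers from the queue
#'
#' For the cluster-margin pretraining variant: each class center is the
#' renormalized mean of that class's queue embeddings, blended with the
#' previous center by a moving average and renormalized again.  A class with
#' no keys in the queue — or a degenerate zero mean — retains its previous
#' center.
#'
#' @param queue A [memory_queue()].
#' @param previous 4 x d matrix of previous centers (rows in canonical class
#'   order), or `NULL` to start from the per-class means alone.
#' @param mu_c Moving-average coefficient in \[0, 1\].
#' @return 4 x d matrix of unit-norm class centers (rows may be `NA` when a
#'   class has never been seen).
#' @export
cluster_margin_centers <- function(queue, previous = NULL, mu_c = 0.9) {
  classes <- cluster_labels()
  d <- ncol(queue$embeddings)
  if (is.null(previous)) previous <- matrix(NA_real_, length(classes), d)
  out <- previous
  for (i in seq_along(classes)) {
    rows <- queue$labels == classes[i]
    if (!any(rows)) next
    m <- colMeans(queue$embeddings[rows, , drop = FALSE])
    nm <- sqrt(sum(m^2))
    if (nm == 0) next  # antipodal keys: degenerate mean, keep previous center
    m <- m / nm
    blended <- if (all(is.finite(previous[i, ]))) mu_c * previous[i, ] + (1 - mu_c) * m else m
    bn <- sqrt(sum(blended^2))
    if (bn == 0) next
    out[i, ] <- blended / bn
  }
  rownames(out) <- classes
  out
}
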