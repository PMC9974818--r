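# ggplot2 display methods for the package's result types.

#' @export
autoplot.supcam_sample <- function(object, ...) {
  img <- object$image
  df <- tibble::tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)),
    y = rep(seq_len(nrow(img)), times = ncol(img)),
    intensity = as.vector(img)
  )
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    scale_y_reverse() +
    coord_equal() +
    labs(title = sprintf("cluster type: %s", object$label), x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.supcam_metrics <- function(object, ...) {
  C <- object$confusion
  df <- tibble::tibble(
    truth = factor(rep(rownames(C), times = ncol(C)), levels = rev(rownames(C))),
    predicted = factor(rep(colnames(C), each = nrow(C)), levels = colnames(C)),
    count = as.vector(C)
  )
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = sprintf("accuracy %.2f%%", object$macro$accuracy)) +
    theme_minimal()
}

#' @export
autoplot.supcam_pretrain <- function(object, ...) {
  ggplot(object$log, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(title = "pretraining loss", x = "epoch", y = "mean batch loss") +
    theme_minimal()
}

#' @export
autoplot.supcam_classifier <- function(object, ...) {
  df <- tidyr_longer(object$log)
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "fine-tuning trajectory") +
    theme_minimal()
}

# minimal long-format helper (train loss + validation accuracy)
tidyr_longer <- function(log) {
  dplyr::bind_rows(
    tibble::tibble(epoch = log$epoch, metric = "train_loss", value = log$train_loss),
    tibble::tibble(epoch = log$epoch, metric = "val_accuracy", value = log$val_accuracy)
  )
}
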