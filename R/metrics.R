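#' Confusion matrix and macro-averaged metrics
#'
#' Builds the true-by-predicted confusion matrix and computes accuracy plus
#' per-class precision, sensitivity, specificity and F1 from one-vs-rest
#' counts; the macro value of each metric is the unweighted mean across
#' classes.  All metrics are reported as percentages rounded to two
#' decimals.  A per-class ratio with a zero denominator (e.g. a class never
#' predicted) is set to 0 before averaging and the event is reported via a
#' message.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class order for the matrix (default [cluster_labels()]).
#' @return A `supcam_metrics` object: `confusion` (matrix, rows = truth),
#'   `per_class` tibble, `macro` named list of percentages, `n`.
#' @export
confusion_and_metrics <- function(truth, predicted, classes = cluster_labels()) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  if (anyNA(truth) || anyNA(predicted)) abort("labels outside the class set")
  C <- table(truth = truth, predicted = predicted)
  C <- matrix(as.integer(C), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  n <- length(truth)

  safe_ratio <- function(num, den, what, cl) {
    if (den == 0) {
      message(sprintf("undefined %s for class \"%s\" (zero denominator); using 0", what, cl))
      return(0)
    }
    num / den
  }
  per <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- C[i, i]
    fp <- sum(C[, i]) - tp
    fn <- sum(C[i, ]) - tp
    tn <- n - tp - fp - fn
    precision <- safe_ratio(tp, tp + fp, "precision", classes[i])
    sensitivity <- safe_ratio(tp, tp + fn, "sensitivity", classes[i])
    specificity <- safe_ratio(tn, tn + fp, "specificity", classes[i])
    f1 <- if (precision + sensitivity == 0) {
      message(sprintf("undefined F1 for class \"%s\"; using 0", classes[i]))
      0
    } else 2 * precision * sensitivity / (precision + sensitivity)
    tibble::tibble(class = classes[i], tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, sensitivity = sensitivity,
                   specificity = specificity, f1 = f1)
  })
  macro <- list(
    accuracy = round(100 * sum(diag(C)) / n, 2),
    precision = round(100 * mean(per$precision), 2),
    sensitivity = round(100 * mean(per$sensitivity), 2),
    specificity = round(100 * mean(per$specificity), 2),
    f1 = round(100 * mean(per$f1), 2)
  )
  structure(list(confusion = C, per_class = per, macro = macro, n = n),
            class = "supcam_metrics")
}

#' @export
print.supcam_metrics <- function(x, ...) {
  cat(sprintf("<supcam_metrics> n = %d\n", x$n))
  cat(sprintf("  accuracy    %6.2f%%\n", x$macro$accuracy))
  cat(sprintf("  precision   %6.2f%%  (macro)\n", x$macro$precision))
  cat(sprintf("  sensitivity %6.2f%%  (macro)\n", x$macro$sensitivity))
  cat(sprintf("  specificity %6.2f%%  (macro)\n", x$macro$specificity))
  cat(sprintf("  F1          %6.2f%%  (macro)\n", x$macro$f1))
  invisible(x)
}

#' @export
tidy.supcam_metrics <- function(x, ...) {
  dplyr::mutate(
    x$per_class,
    dplyr::across(c("precision", "sensitivity", "specificity", "f1"),
                  ~ round(100 * .x, 2))
  )
}

#' @export
glance.supcam_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$macro$accuracy, precision = x$macro$precision,
                 sensitivity = x$macro$sensitivity,
                 specificity = x$macro$specificity, f1 = x$macro$f1, n = x$n)
}

#' @export
tidy.supcam_pretrain <- function(x, ...) x$log

#' @export
glance.supcam_pretrain <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), final_loss = utils::tail(x$log$loss, 1),
                 margin_mode = x$config$margin_mode,
                 queue_capacity = x$config$queue_capacity)
}

#' @export
tidy.supcam_classifier <- function(x, ...) x$log

#' @export
glance.supcam_classifier <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch,
                 best_val_accuracy = if (all(is.na(x$log$val_accuracy))) NA_real_
                                     else max(x$log$val_accuracy, na.rm = TRUE),
                 epochs = nrow(x$log))
}

#' Write evaluation artifacts
#'
#' `write_metrics_json()` stores all five macro metrics plus per-class
#' values; `write_confusion_tsv()` writes the confusion matrix as TSV with
#' labeled header row and column.
#'
#' @param metrics A `supcam_metrics` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(
    list(macro = metrics$macro,
         per_class = tidy(metrics),
         n = metrics$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_confusion_tsv <- function(metrics, path) {
  out <- cbind(truth = rownames(metrics$confusion),
               as.data.frame.matrix(metrics$confusion))
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}
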