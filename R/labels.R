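#' Chromosome cluster type labels
#'
#' The four cluster categories used throughout the package, in canonical
#' order.  `"uncertainty"` is an internal resampling tag used by the
#' category-variant composition look-up tables; it never appears in persisted
#' datasets or in loss computation.
#'
#' @param include_uncertainty If `TRUE`, append the internal `"uncertainty"`
#'   tag to the four real classes.
#' @return Character vector of label strings.
#' @examples
#' cluster_labels()
#' @export
cluster_labels <- function(include_uncertainty = FALSE) {
  lv <- c("instance", "touching", "overlapping", "touching_overlapping")
  if (include_uncertainty) c(lv, "uncertainty") else lv
}

#' @keywords internal
assert_label <- function(label, allow_uncertainty = FALSE, arg = "label") {
  ok <- cluster_labels(include_uncertainty = allow_uncertainty)
  if (!(is.character(label) && length(label) == 1L && label %in% ok)) {
    abort(sprintf("`%s` must be one of: %s (got \"%s\")",
                  arg, paste(ok, collapse = ", "), paste(label, collapse = ",")))
  }
  invisible(label)
}

#' Bundle a grayscale image with its cluster label
#'
#' The unit flowing through composition and training: a numeric matrix of
#' 8-bit intensities (rows = y, columns = x; background exactly 0, foreground
#' in \[1, 255\]) plus one of the four cluster-type labels.
#'
#' @param image Numeric matrix with values in \[0, 255\]; 0 marks background.
#' @param label One of [cluster_labels()].
#' @return An object of class `supcam_sample`.
#' @export
labeled_sample <- function(image, label) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(image < 0) || any(image > 255)) {
    abort("image intensities must lie in [0, 255]")
  }
  assert_label(label)
  structure(list(image = image, label = label), class = "supcam_sample")
}

#' @export
print.supcam_sample <- function(x, ...) {
  cat(sprintf("<supcam_sample> %dx%d, label = %s, foreground px = %d\n",
              nrow(x$image), ncol(x$image), x$label, sum(x$image != 0)))
  invisible(x)
}

#' @rdname labeled_sample
#' @param x Object to test.
#' @export
is_labeled_sample <- function(x) inherits(x, "supcam_sample")
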