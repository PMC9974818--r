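# Category-invariant augmentations used during pretraining (random resized
# crop, horizontal flip) and fine-tuning (random rotation).  All operate on
# intensity matrices with nearest-neighbor resampling and zero background
# fill, so the background stays exactly 0.

#' Random resized crop
#'
#' Samples a sub-rectangle covering a random fraction of the image area
#' (with a random aspect ratio) and rescales it back to the full canvas by
#' nearest-neighbor lookup.
#'
#' @param image Intensity matrix.
#' @param scale Area-fraction bounds of the crop (default `c(0.2, 1)`).
#' @param ratio Aspect-ratio bounds.
#' @return Augmented matrix of the original size.
#' @export
random_resized_crop <- function(image, scale = c(0.2, 1), ratio = c(3 / 4, 4 / 3)) {
  h <- nrow(image); w <- ncol(image)
  for (i in 1:10) {
    area <- runif(1, scale[1], scale[2]) * h * w
    ar <- exp(runif(1, log(ratio[1]), log(ratio[2])))
    ch <- round(sqrt(area / ar)); cw <- round(sqrt(area * ar))
    if (ch >= 1 && cw >= 1 && ch <= h && cw <= w) {
      top <- sample.int(h - ch + 1L, 1L); left <- sample.int(w - cw + 1L, 1L)
      rows <- top + pmin(ch - 1L, floor((seq_len(h) - 1) * ch / h))
      cols <- left + pmin(cw - 1L, floor((seq_len(w) - 1) * cw / w))
      return(image[rows, cols])
    }
  }
  image
}

#' Horizontal flip with probability `p`
#'
#' @param image Intensity matrix.
#' @param p Flip probability (default 0.5).
#' @return Possibly flipped matrix.
#' @export
random_hflip <- function(image, p = 0.5) {
  if (runif(1) < p) image[, rev(seq_len(ncol(image))), drop = FALSE] else image
}

#' Random rotation about the image center
#'
#' Rotates by a uniform angle in `[-degrees, degrees]` with nearest-neighbor
#' resampling and zero fill outside the source.
#'
#' @param image Intensity matrix.
#' @param degrees Maximal absolute rotation (default 180).
#' @return Rotated matrix of the original size.
#' @export
random_rotation <- function(image, degrees = 180) {
  ang <- runif(1, -degrees, degrees) * pi / 180
  rotate_image(image, ang)
}

rotate_image <- function(image, angle) {
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  # inverse map: rotate output coords by -angle into source coords
  sx <- round(cos(angle) * xx + sin(angle) * yy + cx)
  sy <- round(-sin(angle) * xx + cos(angle) * yy + cy)
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  out <- matrix(0, h, w)
  out[ok] <- image[cbind(sy[ok], sx[ok])]
  out
}

# the two category-invariant views used in the pretraining step; crops are
# redrawn until they retain some foreground so views never collapse to an
# empty image
augment_pretrain_view <- function(image, crop_scale = c(0.2, 1)) {
  for (i in 1:10) {
    v <- random_resized_crop(image, scale = crop_scale)
    if (any(v != 0)) return(random_hflip(v))
  }
  random_hflip(image)
}
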