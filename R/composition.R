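#' Composition configuration
#'
#' Parameters of category-variant image composition: the pixel-intersection
#' threshold separating touching from overlapping cases, the resampling
#' budget, the blend used in overlap regions, and the label look-up scheme.
#'
#' @param pixel_intersection_threshold Non-negative integer; a composed pair
#'   with at most this many intersecting foreground pixels is a touching
#'   case, otherwise an overlapping case. Default 200 (for 224x224 images;
#'   scale by `(canvas/224)^2` at other resolutions).
#' @param max_resamples Non-negative integer; upper limit of shift-sampling
#'   rounds before falling back to the candidate sample. Default 10.
#' @param blend_method How overlap-region pixels are blended: `"equal"`
#'   (0.5/0.5), `"lambda_interpolation"` (a Beta(1,1)-drawn ratio), or
#'   `"maximum"`.
#' @param lookup_scheme Label look-up table: `"middle"` (default), `"heavy"`,
#'   `"light"`, or `"none"` (composition disabled; the candidate is returned).
#' @return A `supcam_composition_config` list.
#' @export
composition_config <- function(pixel_intersection_threshold = 200,
                               max_resamples = 10,
                               blend_method = c("equal", "lambda_interpolation", "maximum"),
                               lookup_scheme = c("middle", "heavy", "light", "none")) {
  blend_method <- match.arg(blend_method)
  lookup_scheme <- match.arg(lookup_scheme)
  stopifnot(pixel_intersection_threshold >= 0, max_resamples >= 0)
  structure(
    list(pixel_intersection_threshold = as.integer(pixel_intersection_threshold),
         max_resamples = as.integer(max_resamples),
         blend_method = blend_method,
         lookup_scheme = lookup_scheme),
    class = "supcam_composition_config"
  )
}

#' Foreground indicator mask
#'
#' @param image Numeric matrix; background is exactly 0.
#' @return Integer 0/1 matrix of the same dimensions, 1 where `image != 0`.
#' @export
foreground_mask <- function(image) {
  stopifnot(is.matrix(image))
  m <- matrix(0L, nrow(image), ncol(image))
  m[image != 0] <- 1L
  m
}

#' Bounding box of the foreground
#'
#' Inclusive, 1-based pixel box of all foreground (nonzero) pixels, with
#' x = column and y = row.
#'
#' @param mask Binary (or gray) matrix; nonzero marks foreground.
#' @return List with `min_x`, `max_x`, `min_y`, `max_y`, `width`, `height`.
#' @export
cluster_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty foreground: cannot compute bounding box")
  box <- list(min_x = min(idx[, 2L]), max_x = max(idx[, 2L]),
              min_y = min(idx[, 1L]), max_y = max(idx[, 1L]))
  box$width  <- box$max_x - box$min_x + 1L
  box$height <- box$max_y - box$min_y + 1L
  box
}

#' Shift ranges from two bounding boxes
#'
#' The admissible shift of each image is bounded by the maximum outer
#' enclosing box of the two cluster bounding boxes:
#' `R_i^x = min(W, (W_Bp + W_Bc - W_Bi) / 2)` and analogously in y with the
#' canvas height.
#'
#' @param box_p,box_c Bounding boxes from [cluster_bbox()].
#' @param width,height Canvas dimensions in pixels.
#' @return List with elements `p` and `c`, each `list(rx, ry)`.
#' @export
shift_ranges <- function(box_p, box_c, width, height) {
  rx <- function(own) min(width,  (box_p$width  + box_c$width  - own$width)  / 2)
  ry <- function(own) min(height, (box_p$height + box_c$height - own$height) / 2)
  list(p = list(rx = rx(box_p), ry = ry(box_p)),
       c = list(rx = rx(box_c), ry = ry(box_c)))
}

#' Sample a uniform shift within given ranges
#'
#' Shift biases are drawn uniformly on `[-rx, rx]` and `[-ry, ry]`, defining
#' the pure-translation affine matrix `[[1,0,sx],[0,1,sy]]`.  Uses the current
#' R random stream; seed with [set.seed()] for reproducibility.
#'
#' @param ranges A `list(rx, ry)` of non-negative reals.
#' @return `list(sx, sy)` real shift biases.
#' @export
sample_shift <- function(ranges) {
  stopifnot(ranges$rx >= 0, ranges$ry >= 0)
  list(sx = runif(1L, -ranges$rx, ranges$rx),
       sy = runif(1L, -ranges$ry, ranges$ry))
}

#' Translate an image by an integer-rounded shift
#'
#' Output pixel `(y, x)` takes input pixel `(y - sy, x - sx)` when in bounds
#' and 0 otherwise; shifts are rounded to the nearest integer pixel first, so
#' no interpolation is applied.
#'
#' @param image Numeric matrix.
#' @param shift `list(sx, sy)` (x = columns, y = rows).
#' @return Matrix of the same size.
#' @export
translate_image <- function(image, shift) {
  dx <- round(shift$sx); dy <- round(shift$sy)
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  src_rows <- seq_len(h) - dy
  src_cols <- seq_len(w) - dx
  rkeep <- src_rows >= 1 & src_rows <= h
  ckeep <- src_cols >= 1 & src_cols <= w
  if (any(rkeep) && any(ckeep)) {
    out[which(rkeep), which(ckeep)] <- image[src_rows[rkeep], src_cols[ckeep], drop = FALSE]
  }
  out
}

#' Count intersecting foreground pixels
#'
#' @param a,b Numeric matrices of equal size.
#' @return Number of positions where both images are nonzero.
#' @export
count_pixel_intersection <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("images must have equal dimensions")
  sum(a != 0 & b != 0)
}

#' Combine two images with overlap-region blending
#'
#' Pixels where only one image has foreground are copied unchanged; pixels
#' where both have foreground are blended (`equal`: mean;
#' `lambda_interpolation`: `lambda * a + (1 - lambda) * b`; `maximum`:
#' elementwise max); background stays 0.  Non-overlap foreground is never
#' rescaled.
#'
#' @param a,b Numeric matrices of equal size (warped primary / candidate).
#' @param blend_method See [composition_config()].
#' @param lambda Combination ratio in \[0, 1\]; used only for
#'   `"lambda_interpolation"`.
#' @return Combined matrix.
#' @export
combine_images <- function(a, b, blend_method = "equal", lambda = 0.5) {
  if (!all(dim(a) == dim(b))) abort("images must have equal dimensions")
  fa <- a != 0; fb <- b != 0
  out <- matrix(0, nrow(a), ncol(a))
  out[fa & !fb] <- a[fa & !fb]
  out[fb & !fa] <- b[fb & !fa]
  ov <- fa & fb
  if (any(ov)) {
    out[ov] <- switch(blend_method,
      equal = 0.5 * a[ov] + 0.5 * b[ov],
      lambda_interpolation = {
        stopifnot(lambda >= 0, lambda <= 1)
        lambda * a[ov] + (1 - lambda) * b[ov]
      },
      maximum = pmax(a[ov], b[ov]),
      abort(sprintf("unknown blend method \"%s\"", blend_method))
    )
  }
  out
}
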