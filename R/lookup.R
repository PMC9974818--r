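#' Label look-up for composed images
#'
#' Assigns the class of a composed image from the two source labels and the
#' number of intersecting foreground pixels.  A pair with
#' `n_intersect <= P` (the pixel-intersection threshold) is a *touching
#' case*, otherwise an *overlapping case*; each of the 10 unordered label
#' pairs then maps, per case, to a cluster type or to the internal
#' `"uncertainty"` tag (which triggers shift resampling in [compose_pair()]).
#'
#' Touching case (all schemes): if either source contains an overlap
#' (`overlapping` or `touching_overlapping`) the result is
#' `touching_overlapping`; otherwise (`instance`/`touching` pairs) it is
#' `touching`.
#'
#' Overlapping case: the `middle` table assigns `overlapping` to the
#' instance-instance, overlapping-instance and overlapping-overlapping pairs
#' and `uncertainty` to every other pair; `light` keeps only the
#' instance-instance pair; `heavy` replaces every `middle` uncertainty cell
#' with `touching_overlapping`.
#'
#' @param y_p,y_c Source labels (one of the four real classes; the
#'   `"uncertainty"` tag is not a valid input).
#' @param n_intersect Non-negative intersection pixel count of the two
#'   warped foregrounds.
#' @param config A [composition_config()]; uses its threshold and scheme.
#' @return A label string, possibly `"uncertainty"`.  The function is
#'   symmetric in `(y_p, y_c)`.
#' @export
lookup_label <- function(y_p, y_c, n_intersect, config = composition_config()) {
  assert_label(y_p, arg = "y_p")
  assert_label(y_c, arg = "y_c")
  stopifnot(n_intersect >= 0)
  scheme <- config$lookup_scheme
  if (scheme == "none") {
    abort("lookup_label is not defined for scheme \"none\" (composition disabled)")
  }
  pair <- sort(c(y_p, y_c))
  touching_case <- n_intersect <= config$pixel_intersection_threshold

  if (touching_case) {
    # identical across middle/heavy/light
    if (any(pair %in% c("overlapping", "touching_overlapping"))) {
      return("touching_overlapping")
    }
    return("touching")
  }

  overlap_pairs <- switch(scheme,
    middle = ,
    heavy  = list(c("instance", "instance"),
                  c("instance", "overlapping"),
                  c("overlapping", "overlapping")),
    light  = list(c("instance", "instance"))
  )
  is_overlap <- any(vapply(overlap_pairs, function(p) all(p == pair), logical(1)))
  if (is_overlap) return("overlapping")
  if (scheme == "heavy") "touching_overlapping" else "uncertainty"
}

#' Category-variant image composition of two labeled samples
#'
#' Composes a primary and a candidate sample into a new training sample:
#' foreground bounding boxes bound the admissible shifts (the maximum outer
#' enclosing box rule of [shift_ranges()]); up to `max_resamples` rounds draw
#' uniform shifts for both images, warp them, blend with
#' [combine_images()], count the foreground intersection, and assign a label
#' with [lookup_label()].  The first round yielding a real (non-uncertainty)
#' label is returned; when the budget is exhausted — or the look-up scheme is
#' `"none"` — the candidate sample is returned unchanged.
#'
#' @param primary,candidate [labeled_sample()] objects of equal image size.
#' @param config A [composition_config()].
#' @return A `supcam_sample` with attributes `composed` (logical: was a new
#'   image generated?) and `rounds` (shift-sampling rounds consumed).
#' @export
compose_pair <- function(primary, candidate, config = composition_config()) {
  stopifnot(is_labeled_sample(primary), is_labeled_sample(candidate))
  if (!all(dim(primary$image) == dim(candidate$image))) {
    abort("primary and candidate images must have equal dimensions")
  }
  fallback <- function(rounds) {
    out <- labeled_sample(candidate$image, candidate$label)
    attr(out, "composed") <- FALSE
    attr(out, "rounds") <- rounds
    out
  }
  if (config$lookup_scheme == "none") return(fallback(0L))

  mask_p <- foreground_mask(primary$image)
  mask_c <- foreground_mask(candidate$image)
  if (sum(mask_p) == 0L || sum(mask_c) == 0L) {
    abort("empty foreground in primary or candidate image")
  }
  w <- ncol(mask_p); h <- nrow(mask_p)
  ranges <- shift_ranges(cluster_bbox(mask_p), cluster_bbox(mask_c), w, h)

  n <- 0L
  while (n < config$max_resamples) {
    shift_p <- sample_shift(ranges$p)
    shift_c <- sample_shift(ranges$c)
    warped_p <- translate_image(primary$image, shift_p)
    warped_c <- translate_image(candidate$image, shift_c)
    n <- n + 1L
    if (sum(warped_p != 0) == 0L || sum(warped_c != 0) == 0L) next  # fully cropped
    lambda <- if (config$blend_method == "lambda_interpolation") stats::rbeta(1, 1, 1) else 0.5
    n_int <- count_pixel_intersection(warped_p, warped_c)
    y_g <- lookup_label(primary$label, candidate$label, n_int, config)
    if (y_g != "uncertainty") {
      img <- combine_images(warped_p, warped_c, config$blend_method, lambda)
      out <- labeled_sample(img, y_g)
      attr(out, "composed") <- TRUE
      attr(out, "rounds") <- n
      attr(out, "n_intersect") <- n_int
      return(out)
    }
  }
  fallback(n)
}
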