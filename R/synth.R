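#' Configuration of the synthetic chromosome-cluster generator
#'
#' Describes the study conditions the generator emulates: dark background
#' (exactly 0), banded curved chromosome foregrounds, four cluster classes,
#' and the class imbalance of the clinical reference dataset
#' (1712 : 3029 : 1038 : 813 for instance : touching : overlapping :
#' touching-overlapping).
#'
#' @param canvas_size Square canvas side in pixels (default 224).
#' @param n_per_class Four non-negative integers: images per class in
#'   canonical label order.  Defaults to the reference class counts; use
#'   [scale_class_counts()] for proportionally smaller datasets.
#' @param seed Integer master seed; per-image seeds are derived from it by a
#'   counter, so datasets are reproducible without global state.
#' @param curve_control_points Number of spline control points per
#'   chromosome body (>= 3).
#' @param width_range Pair of positive integers: chromosome band width in
#'   pixels.  Default scales 8–14 px at 224 with the canvas.
#' @param band_count_range Pair of positive integers: longitudinal
#'   intensity bands per chromosome.
#' @param intensity_range Pair of integers in \[1, 255\]: foreground
#'   intensity band (0 is reserved for background).
#' @param class_ratios Four non-negative reals; relative class frequencies
#'   (default proportional to the reference counts).
#' @param pixel_intersection_threshold Ground-truth intersection threshold
#'   used to realize class geometry; defaults to `200 * (canvas_size/224)^2`
#'   so labels stay consistent at small canvases.
#' @param max_retries Bounded number of placement retries per cluster.
#' @return A `supcam_synth_config` list.
#' @export
synth_config <- function(canvas_size = 224,
                         n_per_class = c(1712, 3029, 1038, 813),
                         seed = 1L,
                         curve_control_points = 5,
                         width_range = NULL,
                         band_count_range = c(4, 9),
                         intensity_range = c(60, 230),
                         class_ratios = c(1712, 3029, 1038, 813),
                         pixel_intersection_threshold = NULL,
                         max_retries = 10) {
  if (is.null(width_range)) {
    width_range <- pmax(3, round(canvas_size * c(8, 14) / 224))
  }
  if (is.null(pixel_intersection_threshold)) {
    pixel_intersection_threshold <- round(200 * (canvas_size / 224)^2)
  }
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 0),
            length(class_ratios) == 4, all(class_ratios >= 0),
            curve_control_points >= 3,
            length(width_range) == 2, all(width_range > 0),
            width_range[1] <= width_range[2],
            length(band_count_range) == 2, all(band_count_range > 0),
            length(intensity_range) == 2,
            max_retries >= 0)
  if (intensity_range[1] < 1 || intensity_range[2] > 255) {
    abort("intensity_range must lie within [1, 255]; 0 is reserved for background")
  }
  if (canvas_size < 2 * max(width_range)) {
    abort("canvas_size must be at least twice the maximum chromosome width")
  }
  structure(
    list(canvas_size = as.integer(canvas_size),
         n_per_class = as.integer(round(n_per_class)),
         seed = as.integer(seed),
         curve_control_points = as.integer(curve_control_points),
         width_range = as.integer(width_range),
         band_count_range = as.integer(band_count_range),
         intensity_range = as.integer(intensity_range),
         class_ratios = as.numeric(class_ratios),
         pixel_intersection_threshold = as.integer(pixel_intersection_threshold),
         max_retries = as.integer(max_retries)),
    class = "supcam_synth_config"
  )
}

#' Scale the reference class counts
#'
#' Nearest-integer scaling of four class counts (default: the reference
#' imbalance 1712/3029/1038/813) by a common factor.
#'
#' @param factor Positive scaling factor (e.g. `1/100`).
#' @param ratios Four non-negative reals.
#' @return Four integers.
#' @export
scale_class_counts <- function(factor, ratios = c(1712, 3029, 1038, 813)) {
  as.integer(round(ratios * factor))
}

#' Label 4-connected foreground components
#'
#' Iterative minimum-label propagation over the 4-neighborhood; vectorized,
#' so runtime scales with image size times component diameter.
#'
#' @param mask Matrix; nonzero marks foreground.
#' @return Integer matrix: 0 on background, a positive component id
#'   (renumbered 1..k) on foreground.
#' @export
label_components <- function(mask) {
  fg <- mask != 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(Inf, h, w)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    nb <- lab
    nb[-1, ]  <- pmin(nb[-1, ],  lab[-h, ])   # from above
    nb[-h, ]  <- pmin(nb[-h, ],  lab[-1, ])   # from below
    nb[, -1]  <- pmin(nb[, -1],  lab[, -w])   # from left
    nb[, -w]  <- pmin(nb[, -w],  lab[, -1])   # from right
    nb[!fg] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, h, w)
  if (any(fg)) {
    ids <- sort(unique(lab[fg]))
    out[fg] <- match(lab[fg], ids)
  }
  out
}

#' @rdname label_components
#' @export
count_components <- function(mask) {
  max(label_components(mask))
}

# uniform integer draw on an inclusive range (safe for degenerate ranges,
# unlike sample() on a scalar)
sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

# Rasterize one banded curved chromosome body onto a blank canvas.
# Uses the current RNG stream.  Returns the image with a `meta` attribute
# holding the sampled width, arc length, band count and generator-computed
# foreground-count bounds.
draw_chromosome <- function(config) {
  n <- config$canvas_size
  width <- sample_range(config$width_range)
  r <- width / 2
  margin <- max(config$width_range) + ceiling(0.05 * n)
  k <- config$curve_control_points
  # each body lives in a random sub-window of the canvas so that clusters
  # can be assembled with room to slide the parts into contact
  extent <- max(4 * width, runif(1, 0.35, 0.6) * n)
  extent <- min(extent, n - 2 * margin - 1)
  x0 <- runif(1, margin + 1, n - margin - extent)
  y0 <- runif(1, margin + 1, n - margin - extent)
  # control points swept along a random direction to give a smooth open curve
  px <- runif(k, x0, x0 + extent)
  py <- runif(k, y0, y0 + extent)
  dir <- runif(1, 0, pi)
  ord <- order(px * cos(dir) + py * sin(dir))
  px <- px[ord]; py <- py[ord]
  t_dense <- seq(1, k, length.out = 4L * n)
  cx <- spline(seq_len(k), px, xout = t_dense)$y
  cy <- spline(seq_len(k), py, xout = t_dense)$y
  lim <- c(r + 1, n - r)
  cx <- pmin(pmax(cx, lim[1]), lim[2])
  cy <- pmin(pmax(cy, lim[1]), lim[2])
  arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
  total_len <- arc[length(arc)]

  bands <- sample_range(config$band_count_range)
  phase <- runif(1, 0, 2 * pi)
  lo <- config$intensity_range[1]; hi <- config$intensity_range[2]
  vals <- round(lo + (hi - lo) * (0.5 + 0.5 * cos(2 * pi * bands * arc / max(total_len, 1) + phase)))
  vals <- pmin(pmax(vals, lo), hi)

  off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  img <- matrix(0, n, n)
  rx <- round(cx); ry <- round(cy)
  for (i in seq_len(nrow(off))) {
    rr <- ry + off$dy[i]; cc <- rx + off$dx[i]
    keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    img[cbind(rr[keep], cc[keep])] <- vals[keep]
  }
  n_centers <- nrow(unique(cbind(ry, rx)))
  attr(img, "meta") <- list(
    width = width, arc_length = total_len, bands = bands,
    fg_bounds = c(nrow(off), n_centers * nrow(off))
  )
  img
}

#' Generate one single-chromosome ("instance") sample
#'
#' Draws a smooth cubic-spline curve through random control points, dilates
#' it by a disc of the sampled width and applies sinusoidal longitudinal
#' intensity banding.  The result is a single 4-connected foreground
#' component entirely inside the canvas, on an exactly-zero background.
#' Uses the current RNG stream; seed with [set.seed()].
#'
#' @param config A [synth_config()].
#' @return A `supcam_sample` labeled `"instance"`; its image carries a
#'   `meta` attribute with the sampled geometry and the generator's own
#'   foreground-pixel-count bounds (`fg_bounds`).
#' @export
make_instance <- function(config = synth_config()) {
  img <- draw_chromosome(config)
  labeled_sample(img, "instance")
}

# TRUE when two disjoint logical masks have 4-adjacent foreground pixels
masks_adjacent <- function(a, b) {
  h <- nrow(a); w <- ncol(a)
  (any(a[-1, ] & b[-h, ]) || any(a[-h, ] & b[-1, ]) ||
   any(a[, -1] & b[, -w]) || any(a[, -w] & b[, -1]))
}

# Largest integer t along direction (ux, uy) for which `pred(t)` holds,
# searched by bisection between t_lo (holds) and t_hi (fails).
bisect_largest <- function(pred, t_lo, t_hi) {
  while (t_hi - t_lo > 1L) {
    mid <- (t_lo + t_hi) %/% 2L
    if (pred(mid)) t_lo <- mid else t_hi <- mid
  }
  t_lo
}

# Slide `part` along random directions relative to `base` until the
# requested contact predicate holds. Returns the translated part image or
# NULL on failure.
place_relative <- function(base, part, mode, thr, n_directions = 8L) {
  n <- nrow(base)
  part_fg <- sum(part != 0)
  for (d in seq_len(n_directions)) {
    ang <- runif(1, 0, 2 * pi)
    ux <- cos(ang); uy <- sin(ang)
    shifted <- function(t) translate_image(part, list(sx = t * ux, sy = t * uy))
    intact <- function(img) sum(img != 0) == part_fg
    # base and part are each 4-connected by construction, so the union is
    # connected iff the foregrounds intersect or are 4-adjacent
    connected <- function(img) {
      count_pixel_intersection(base, img) > 0L || masks_adjacent(base != 0, img != 0)
    }

    # separation distance where the two are fully disjoint but the part intact
    t_max <- NA_integer_
    for (t in 0:n) {
      img <- shifted(t)
      if (!intact(img)) break
      if (count_pixel_intersection(base, img) == 0L && !connected(img)) { t_max <- t; break }
    }
    if (mode == "touching") {
      if (is.na(t_max) || !connected(shifted(0L))) next
      t_c <- bisect_largest(function(t) connected(shifted(t)), 0L, t_max)
      img <- shifted(t_c)
      if (count_pixel_intersection(base, img) <= thr && connected(img) && intact(img)) return(img)
      next
    }
    # overlapping: smallest overlap still above the threshold, one crossing region
    over <- function(img) count_pixel_intersection(base, img) > thr
    if (!over(shifted(0L))) next
    t_hi <- if (is.na(t_max)) n else t_max
    t_o <- bisect_largest(function(t) { img <- shifted(t); intact(img) && over(img) }, 0L, t_hi)
    img <- shifted(t_o)
    crossing <- count_components((base != 0) & (img != 0)) == 1L
    if (over(img) && crossing && intact(img) && connected(img)) return(img)
  }
  NULL
}

#' Generate a multi-chromosome cluster sample
#'
#' Composes two or three generated chromosome bodies with controlled
#' placement so that the requested ground-truth label holds by construction:
#' `touching` means the foregrounds are 4-connected with a pixel
#' intersection at most the configured threshold; `overlapping` means the
#' intersection exceeds the threshold with a single crossing region;
#' `touching_overlapping` requires both a touching contact and a crossing
#' region.  Placement is retried up to `config$max_retries` times and errors
#' if the geometry cannot be realized.
#'
#' @param config A [synth_config()].
#' @param target_label `"touching"`, `"overlapping"` or
#'   `"touching_overlapping"`.
#' @return A `supcam_sample`; attribute `parts` holds the pre-blend
#'   translated component images so label predicates can be re-checked.
#' @export
make_cluster <- function(config = synth_config(),
                         target_label = c("touching", "overlapping", "touching_overlapping")) {
  target_label <- match.arg(target_label)
  thr <- config$pixel_intersection_threshold
  for (attempt in seq_len(config$max_retries)) {
    a <- draw_chromosome(config)
    b <- draw_chromosome(config)
    if (target_label %in% c("touching", "overlapping")) {
      placed <- place_relative(a, b, mode = if (target_label == "touching") "touching" else "overlapping", thr = thr)
      if (is.null(placed)) next
      img <- combine_images(a, placed, "equal")
      out <- labeled_sample(img, target_label)
      attr(out, "parts") <- list(a, placed)
      return(out)
    }
    # touching_overlapping: b overlaps a, then c touches the pair
    placed_b <- place_relative(a, b, mode = "overlapping", thr = thr)
    if (is.null(placed_b)) next
    base <- combine_images(a, placed_b, "equal")
    cc <- draw_chromosome(config)
    placed_c <- place_relative(base, cc, mode = "touching", thr = thr)
    if (is.null(placed_c)) next
    img <- combine_images(base, placed_c, "equal")
    out <- labeled_sample(img, target_label)
    attr(out, "parts") <- list(a, placed_b, placed_c)
    return(out)
  }
  abort(sprintf("could not realize \"%s\" geometry within %d retries",
                target_label, config$max_retries))
}

#' Write a synthetic labeled dataset to disk
#'
#' Generates `config$n_per_class` images per class (instance via
#' [make_instance()], clusters via [make_cluster()]), writes them as 8-bit
#' grayscale PNGs and returns the `path,label` manifest, which is also
#' written as `manifest.csv` in `out_dir`.  Each image uses a seed derived
#' from `config$seed` and a running counter, so re-running with the same
#' configuration reproduces identical files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return A tibble with columns `path` (relative to `out_dir`) and `label`,
#'   invisibly carrying attribute `manifest_path`.
#' @export
make_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory: %s", out_dir))
  labels <- cluster_labels()
  rows <- list()
  counter <- 0L
  for (ci in seq_along(labels)) {
    for (i in seq_len(config$n_per_class[ci])) {
      counter <- counter + 1L
      set.seed((config$seed + 7919L * counter) %% 2147483647L)
      smp <- if (labels[ci] == "instance") make_instance(config) else make_cluster(config, labels[ci])
      fname <- sprintf("%s_%05d.png", labels[ci], i)
      write_gray_png(smp$image, file.path(out_dir, fname))
      rows[[counter]] <- tibble::tibble(path = fname, label = labels[ci])
    }
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(path = character(), label = character())
  mpath <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  attr(manifest, "manifest_path") <- mpath
  attr(manifest, "base_dir") <- out_dir
  manifest
}
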