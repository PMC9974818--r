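test_that("foreground mask is the nonzero indicator", {
  expect_equal(foreground_mask(matrix(0, 5, 5)), matrix(0L, 5, 5))

  img <- matrix(0, 8, 8)
  img[4, 3] <- 5  # y = 4, x = 3
  m <- foreground_mask(img)
  expect_equal(sum(m), 1L)
  expect_equal(m[4, 3], 1L)

  withr::with_seed(1, {
    smp <- make_instance(tiny_cfg())
    # brute-force pixel scan
    expect_equal(sum(foreground_mask(smp$image)),
                 sum(apply(smp$image, c(1, 2), function(v) v != 0)))
  })
})

test_that("bounding box equals the exhaustive min/max scan", {
  img <- matrix(0, 10, 10)
  img[4, 3] <- 1
  box <- cluster_bbox(img)
  expect_equal(box[c("min_x", "max_x", "min_y", "max_y")],
               list(min_x = 3, max_x = 3, min_y = 4, max_y = 4))
  expect_equal(box$width, 1)
  expect_equal(box$height, 1)

  img2 <- matrix(0, 10, 10)
  img2[2, 1] <- 1; img2[7, 5] <- 1  # (x=1,y=2) and (x=5,y=7)
  box2 <- cluster_bbox(img2)
  expect_equal(unlist(box2[c("min_x", "max_x", "min_y", "max_y")]),
               c(min_x = 1, max_x = 5, min_y = 2, max_y = 7))

  withr::with_seed(7, {
    m <- matrix(rbinom(400, 1, 0.1), 20, 20)
    m[1, 1] <- 1
    idx <- which(m == 1, arr.ind = TRUE)
    box3 <- cluster_bbox(m)
    expect_equal(box3$min_x, min(idx[, 2])); expect_equal(box3$max_x, max(idx[, 2]))
    expect_equal(box3$min_y, min(idx[, 1])); expect_equal(box3$max_y, max(idx[, 1]))
  })

  expect_error(cluster_bbox(matrix(0, 3, 3)), "empty foreground")
})

test_that("shift ranges follow the outer-enclosing-box formula", {
  mk <- function(w, h) list(width = w, height = h)
  r <- shift_ranges(mk(40, 40), mk(60, 60), 224, 224)
  expect_equal(r$p$rx, 30)  # min(224, (40+60-40)/2)
  expect_equal(r$c$rx, 20)

  r2 <- shift_ranges(mk(1, 1), mk(1, 1), 224, 224)
  expect_equal(r2$p$rx, 0.5)
  expect_equal(r2$c$rx, 0.5)

  r3 <- shift_ranges(mk(20, 20), mk(20, 20), 8, 8)
  expect_equal(r3$p$rx, 8)  # clamped by the canvas
  expect_equal(r3$c$ry, 8)
})

test_that("sampled shifts are uniform on [-R, R] and reproducible", {
  expect_equal(sample_shift(list(rx = 0, ry = 0)), list(sx = 0, sy = 0))

  withr::with_seed(11, {
    draws <- replicate(10000, sample_shift(list(rx = 10, ry = 10))$sx)
  })
  expect_lt(abs(mean(draws)), 0.5)
  expect_true(min(draws) >= -10 && min(draws) <= -9)
  expect_true(max(draws) >= 9 && max(draws) <= 10)

  s1 <- withr::with_seed(5, sample_shift(list(rx = 3, ry = 3)))
  s2 <- withr::with_seed(5, sample_shift(list(rx = 3, ry = 3)))
  expect_identical(s1, s2)
})

test_that("integer translation moves, crops and zero-fills", {
  img <- matrix(0, 10, 10)
  img[4, 3] <- 9
  expect_equal(translate_image(img, list(sx = 0, sy = 0)), img)

  out <- translate_image(img, list(sx = 2, sy = -1))
  expect_equal(sum(out != 0), 1)
  expect_equal(out[3, 5], 9)  # (x=3+2, y=4-1)

  gone <- translate_image(img, list(sx = 20, sy = 0))
  expect_equal(sum(gone), 0)
})

test_that("pixel intersection counting matches a brute-force scan", {
  a <- matrix(0, 6, 6); b <- matrix(0, 6, 6)
  a[1:3, 1] <- 1; b[1:3, 6] <- 1
  expect_equal(count_pixel_intersection(a, b), 0)
  expect_equal(count_pixel_intersection(a, a), 3)

  withr::with_seed(3, {
    x <- matrix(rbinom(900, 1, 0.3) * 100, 30, 30)
    y <- matrix(rbinom(900, 1, 0.3) * 50, 30, 30)
    brute <- 0
    for (i in 1:30) for (j in 1:30) brute <- brute + (x[i, j] > 0 && y[i, j] > 0)
    expect_equal(count_pixel_intersection(x, y), brute)
  })
  expect_error(count_pixel_intersection(a, matrix(0, 3, 3)), "equal dimensions")
})

test_that("blend semantics: copy outside overlap, blend inside", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[2, 2] <- 100; b[2, 2] <- 50   # overlap pixel
  a[1, 1] <- 80                   # a-only
  b[4, 4] <- 60                   # b-only

  eq <- combine_images(a, b, "equal")
  expect_equal(eq[2, 2], 75)
  expect_equal(eq[1, 1], 80)
  expect_equal(eq[4, 4], 60)

  li <- combine_images(a, b, "lambda_interpolation", lambda = 0.3)
  expect_equal(li[2, 2], 65)
  expect_equal(li[1, 1], 80)  # non-overlap foreground never scaled

  mx <- combine_images(a, b, "maximum")
  expect_equal(mx[2, 2], 100)

  # disjoint foregrounds: union identical to a + b for every method
  a2 <- matrix(0, 4, 4); b2 <- matrix(0, 4, 4)
  a2[1, ] <- 30; b2[3, ] <- 40
  for (m in c("equal", "lambda_interpolation", "maximum")) {
    expect_equal(combine_images(a2, b2, m, lambda = 0.7), a2 + b2)
  }
})

test_that("foreground is conserved through every blend method", {
  # |fg(I_g)| = |fg(I_p)| + |fg(I_c)| - n_intersect, over random synthetic pairs
  cfg <- tiny_cfg()
  withr::with_seed(99, {
    for (rep in 1:25) {
      p <- make_instance(cfg)$image
      c_ <- make_instance(cfg)$image
      n_int <- count_pixel_intersection(p, c_)
      for (m in c("equal", "lambda_interpolation", "maximum")) {
        g <- combine_images(p, c_, m, lambda = runif(1))
        expect_equal(sum(g != 0), sum(p != 0) + sum(c_ != 0) - n_int)
        # never creates foreground on shared background, never zeroes foreground
        expect_true(all(g[p == 0 & c_ == 0] == 0))
        expect_true(all(g[p != 0 | c_ != 0] != 0))
      }
    }
  })
})

test_that("compose_pair honors its fallback and composition contracts", {
  cfg <- tiny_cfg()
  withr::with_seed(21, {
    p <- make_instance(cfg)
    c_ <- make_cluster(cfg, "touching")
  })

  # N = 0: loop never entered, candidate returned unchanged
  out0 <- compose_pair(p, c_, composition_config(max_resamples = 0))
  expect_identical(out0$image, c_$image)
  expect_identical(out0$label, c_$label)
  expect_false(attr(out0, "composed"))

  # scheme none: composition disabled
  outn <- compose_pair(p, c_, composition_config(lookup_scheme = "none"))
  expect_identical(outn$image, c_$image)
  expect_false(attr(outn, "composed"))

  expect_error(
    compose_pair(labeled_sample(matrix(0, nrow(p$image), ncol(p$image)), "instance"),
                 p, composition_config()),
    "empty foreground"
  )

  # successfully composed outputs are never instance or uncertainty and
  # conserve foreground given the recorded intersection
  withr::with_seed(33, {
    for (i in 1:10) {
      a <- make_instance(cfg)
      b <- make_instance(cfg)
      out <- compose_pair(a, b, composition_config(
        pixel_intersection_threshold = cfg$pixel_intersection_threshold))
      if (isTRUE(attr(out, "composed"))) {
        expect_false(out$label %in% c("instance", "uncertainty"))
      }
    }
  })
})

test_that("a forced full-overlap composition is labeled overlapping deterministically", {
  # single-pixel foregrounds: shift ranges collapse to (0.5, 0.5), every
  # uniform draw in (-0.5, 0.5) rounds to a zero shift, so the two pixels
  # must coincide, exceeding a zero intersection threshold in one round
  img <- matrix(0, 32, 32)
  img[16, 16] <- 100
  a <- labeled_sample(img, "instance")
  b <- labeled_sample(img, "instance")
  cfgc <- composition_config(pixel_intersection_threshold = 0, max_resamples = 1)
  withr::with_seed(2, {
    out <- compose_pair(a, b, cfgc)
  })
  expect_true(attr(out, "composed"))
  expect_identical(out$label, "overlapping")
  expect_equal(attr(out, "n_intersect"), 1)
  # the composed image is the blended union of the two coincident pixels
  expect_equal(sum(out$image != 0), 1)
  expect_equal(out$image[16, 16], 100)
})
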