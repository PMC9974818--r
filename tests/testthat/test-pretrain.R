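make_pairs <- function(samples, idx, cand) {
  Map(function(i, j) list(primary = samples[[i]], candidate = samples[[j]]), idx, cand)
}

test_that("one pretraining step grows the queue by two keys per pair", {
  samples <- local_sample_pool()
  cfg <- pretrain_config(batch_size = 4, queue_capacity = 64,
                         embed_dim = 16, hidden = 12, pool_grid = 4, seed = 1)
  comp <- composition_config(pixel_intersection_threshold = 9)
  withr::with_seed(1, {
    state <- pretrain_state_init(cfg, 48)
    state$queue <- memory_queue(64, 16, init = "empty")
    pairs <- make_pairs(samples, 1:4, 5:8)
    st <- pretrain_step(pairs, state, comp, lr = 0.01)
    expect_equal(queue_size(st$state$queue), 8)
    expect_true(is.finite(st$loss))
    st2 <- pretrain_step(pairs, st$state, comp, lr = 0.01)
    expect_equal(queue_size(st2$state$queue), 16)
  })
})

test_that("a step is deterministic given the seed and updates only f_q by gradients", {
  samples <- local_sample_pool()
  cfg <- pretrain_config(batch_size = 4, queue_capacity = 32, embed_dim = 16,
                         hidden = 12, pool_grid = 4, encoder_momentum = 0.999)
  comp <- composition_config(pixel_intersection_threshold = 9)
  run_once <- function() {
    withr::with_seed(7, {
      state <- pretrain_state_init(cfg, 48)
      pairs <- make_pairs(samples, c(1, 7, 13, 19), c(2, 8, 14, 20))
      pretrain_step(pairs, state, comp, lr = 0.01)
    })
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$loss, b$loss)
  expect_identical(a$state$f_q$params, b$state$f_q$params)

  # f_k after the step equals the exact momentum average (zero drift)
  withr::with_seed(7, {
    state <- pretrain_state_init(cfg, 48)
    f_k_old <- state$f_k
    pairs <- make_pairs(samples, c(1, 7, 13, 19), c(2, 8, 14, 20))
    st <- pretrain_step(pairs, state, comp, lr = 0.01)
    mu <- cfg$encoder_momentum
    for (nm in names(f_k_old$params)) {
      expect_equal(st$state$f_k$params[[nm]],
                   mu * f_k_old$params[[nm]] + (1 - mu) * st$state$f_q$params[[nm]],
                   tolerance = 0)
    }
  })
})

test_that("all margin heads produce finite losses and their expected state", {
  samples <- local_sample_pool()
  comp <- composition_config(pixel_intersection_threshold = 9)
  for (mode in c("self", "parametric", "cluster", "none")) {
    cfg <- pretrain_config(batch_size = 4, queue_capacity = 32, embed_dim = 16,
                           hidden = 12, pool_grid = 4, margin_mode = mode)
    withr::with_seed(11, {
      state <- pretrain_state_init(cfg, 48)
      pairs <- make_pairs(samples, 1:4, 21:24)
      st <- pretrain_step(pairs, state, comp, lr = 0.01)
      expect_true(is.finite(st$loss), info = mode)
      if (mode == "parametric") {
        expect_false(identical(st$state$class_weights, state$class_weights))
      }
    })
  }
})

test_that("with margin 0 and composition off, the step loss is supcon plus a self InfoNCE term", {
  samples <- local_sample_pool()
  comp_off <- composition_config(lookup_scheme = "none")
  cfg_m0 <- pretrain_config(batch_size = 4, queue_capacity = 32, embed_dim = 16,
                            hidden = 12, pool_grid = 4, margin = 0)
  cfg_none <- pretrain_config(batch_size = 4, queue_capacity = 32, embed_dim = 16,
                              hidden = 12, pool_grid = 4, margin_mode = "none")
  loss_of <- function(cfg) {
    withr::with_seed(13, {
      state <- pretrain_state_init(cfg, 48)
      pairs <- make_pairs(samples, 1:4, 9:12)
      # frozen encoders: no update influence, just the loss value
      pretrain_step(pairs, state, comp_off, lr = 0)$loss
    })
  }
  full <- loss_of(cfg_m0)
  supcon_only <- loss_of(cfg_none)
  # identical RNG stream -> identical views/keys; the difference is the
  # margin-free self term, itself an InfoNCE value, hence positive
  expect_gt(full, supcon_only)
})

test_that("a 50-step smoke run stays finite and trends downward", {
  withr::with_seed(4242, {
    cfg64 <- synth_config(canvas_size = 64)
    samples <- unlist(lapply(cluster_labels(), function(l) {
      lapply(1:16, function(i) {
        if (l == "instance") make_instance(cfg64) else make_cluster(cfg64, l)
      })
    }), recursive = FALSE)
  })
  comp <- composition_config(pixel_intersection_threshold = 16)
  cfg <- pretrain_config(epochs = 13, warmup_epochs = 2, batch_size = 16,
                         queue_capacity = 128, seed = 11)
  withr::with_seed(cfg$seed, {
    state <- pretrain_state_init(cfg, 64)
    losses <- numeric(0)
    for (e in seq_len(cfg$epochs)) {
      lr <- supcam:::pretrain_lr(cfg, e)
      ord <- sample.int(64)
      for (b in seq(1, 64, 16)) {
        idx <- ord[b:(b + 15)]
        cand <- sample.int(64, 16, replace = TRUE)
        st <- pretrain_step(make_pairs(samples, idx, cand), state, comp, lr)
        state <- st$state
        losses <- c(losses, st$loss)
        if (length(losses) >= 50) break
      }
      if (length(losses) >= 50) break
    }
  })
  expect_true(all(is.finite(losses)))
  # trend over windows after the queue warm-fills
  expect_lt(mean(losses[36:50]), mean(losses[11:25]))
})

test_that("the learning rate schedule warms up linearly then anneals to zero", {
  cfg <- pretrain_config(epochs = 10, warmup_epochs = 4, base_lr = 0.03)
  lrs <- vapply(1:10, function(e) supcam:::pretrain_lr(cfg, e), numeric(1))
  expect_equal(lrs[1:4], 0.03 * (1:4) / 4)
  expect_equal(lrs[10], 0)
  expect_true(all(diff(lrs[4:10]) < 0))
})
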