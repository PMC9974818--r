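test_that("cosine angle handles aligned, orthogonal and antipodal pairs", {
  q <- c(1, 0, 0)
  expect_equal(cosine_angle(q, q), 0, tolerance = 1e-3)
  expect_equal(cosine_angle(q, c(0, 1, 0)), pi / 2)
  expect_equal(cosine_angle(q, -q), pi, tolerance = 1e-3)
  expect_error(cosine_angle(q, c(0, 0, 0)), "zero-norm")
})

test_that("InfoNCE matches its closed forms", {
  # q.k_p = 1, one negative with q.k = 0, tau = 1
  q <- c(1, 0); kp <- c(1, 0); kn <- matrix(c(0, 1), 1)
  expect_equal(info_nce_loss(q, kp, kn, temperature = 1), log(1 + exp(-1)),
               tolerance = 1e-12)

  # all similarities equal with K negatives -> log(1 + K)
  for (K in c(1, 4, 16)) {
    negs <- matrix(rep(c(1, 0), K), K, 2, byrow = TRUE)
    expect_equal(info_nce_loss(q, kp, negs, temperature = 0.3), log(1 + K),
                 tolerance = 1e-12)
  }

  # tau -> 0 with the positive strictly largest: loss -> 0
  kn2 <- matrix(c(sqrt(0.5), sqrt(0.5)), 1)
  expect_lt(info_nce_loss(q, kp, kn2, temperature = 1e-3), 1e-10)

  expect_error(info_nce_loss(q, kp, matrix(numeric(0), 0, 2)), "negative")
})

test_that("SupCon averages per-positive InfoNCE terms with per-term denominators", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      d <- 32
      q <- rand_unit(d)
      P <- rand_unit_rows(3, d)
      K <- rand_unit_rows(5, d)
      brute <- mean(vapply(1:3, function(i) {
        info_nce_loss(q, P[i, ], K, temperature = 0.07)
      }, numeric(1)))
      expect_equal(supcon_loss(q, P, K, temperature = 0.07), brute,
                   tolerance = 1e-10)
    }
  })

  # |K_P| = 1 reduces exactly to InfoNCE
  withr::with_seed(9, {
    q <- rand_unit(16); kp <- rand_unit(16); K <- rand_unit_rows(4, 16)
    expect_equal(supcon_loss(q, matrix(kp, 1), K, 0.07),
                 info_nce_loss(q, kp, K, 0.07), tolerance = 1e-12)
  })

  # equal similarities: log(1 + K) regardless of the positive count
  q <- c(1, 0)
  P <- matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE)
  K <- matrix(rep(c(1, 0), 7), 7, 2, byrow = TRUE)
  expect_equal(supcon_loss(q, P, K, 0.5), log(8), tolerance = 1e-12)
  expect_error(supcon_loss(q, matrix(numeric(0), 0, 2), K), "positive")
})

test_that("self-margin with m = 0 is InfoNCE to 1e-9 over 1000 random inputs", {
  withr::with_seed(123, {
    worst <- 0
    for (rep in 1:1000) {
      d <- 8
      q <- rand_unit(d); kp <- rand_unit(d); K <- rand_unit_rows(3, d)
      a <- self_margin_loss(q, kp, K, loss_params(temperature = 0.07, margin = 0))
      b <- info_nce_loss(q, kp, K, temperature = 0.07)
      worst <- max(worst, abs(a - b))
    }
    expect_lte(worst, 1e-9)
  })
})

test_that("self-margin closed form and monotonicity in the margin", {
  # q = k_+, one orthogonal negative, m = 0.2, tau = 0.07
  q <- c(1, 0); kn <- matrix(c(0, 1), 1)
  v <- self_margin_loss(q, q, kn, loss_params(0.07, 0.2))
  expect_equal(v, log(1 + exp(-cos(0.2) / 0.07)), tolerance = 1e-2)

  # loss increases in m while theta + m <= pi
  withr::with_seed(31, {
    q <- rand_unit(12); kp <- rand_unit(12); K <- rand_unit_rows(6, 12)
    theta <- cosine_angle(q, kp)
    ms <- seq(0, pi - theta - 0.01, length.out = 8)
    vals <- vapply(ms, function(m) {
      self_margin_loss(q, kp, K, loss_params(0.07, m))
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  })
})

test_that("additive angular margin loss matches its closed forms", {
  # m = 0, all angles equal -> log(n_classes)
  q <- c(1, 0, 0)
  W <- rand_unit_rows(4, 3)
  Weq <- matrix(rep(c(0, 1, 0), 4), 4, 3, byrow = TRUE)
  expect_equal(additive_angular_margin_loss(q, Weq, 1, loss_params(0.07, 0)),
               log(4), tolerance = 1e-10)

  # binary case: theta_true = 0, theta_other = pi/2
  W2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(additive_angular_margin_loss(q, W2, 1, loss_params(0.07, 0.2)),
               log(1 + exp(-cos(0.2) / 0.07)), tolerance = 1e-2)

  expect_error(additive_angular_margin_loss(q, W2, 3, loss_params()), "out of range")
})

test_that("analytic gradients match finite differences at 100 random configurations", {
  withr::with_seed(2024, {
    worst <- c(infonce = 0, supcon = 0, selfmargin = 0, aam = 0)
    for (rep in 1:25) {
      d <- 10
      q <- rnorm(d)  # deliberately non-unit: gradients flow through normalization
      kp <- rand_unit(d)
      P <- rand_unit_rows(3, d)
      K <- rand_unit_rows(4, d)
      W <- rand_unit_rows(4, d)
      params <- loss_params(temperature = 0.2, margin = 0.15)
      cases <- list(
        infonce = list(
          f = function(x) info_nce_loss(x, kp, K, 0.2),
          g = info_nce_loss(q, kp, K, 0.2, grad = TRUE)$grad_q),
        supcon = list(
          f = function(x) supcon_loss(x, P, K, 0.2),
          g = supcon_loss(q, P, K, 0.2, grad = TRUE)$grad_q),
        selfmargin = list(
          f = function(x) self_margin_loss(x, kp, K, params),
          g = self_margin_loss(q, kp, K, params, grad = TRUE)$grad_q),
        aam = list(
          f = function(x) additive_angular_margin_loss(x, W, 2, params),
          g = additive_angular_margin_loss(q, W, 2, params, grad = TRUE)$grad_q)
      )
      for (nm in names(cases)) {
        fd <- fd_grad(cases[[nm]]$f, q)
        rel <- max(abs(cases[[nm]]$g - fd)) / max(max(abs(fd)), 1e-8)
        worst[nm] <- max(worst[nm], rel)
      }
    }
    expect_true(all(worst <= 1e-4))
  })
})

test_that("losses are permutation invariant and non-negative", {
  withr::with_seed(47, {
    for (rep in 1:20) {
      d <- 16
      q <- rand_unit(d); kp <- rand_unit(d)
      P <- rand_unit_rows(4, d); K <- rand_unit_rows(6, d)
      perm_k <- sample(6); perm_p <- sample(4)
      expect_equal(info_nce_loss(q, kp, K, 0.07),
                   info_nce_loss(q, kp, K[perm_k, ], 0.07), tolerance = 1e-12)
      expect_equal(supcon_loss(q, P, K, 0.07),
                   supcon_loss(q, P[perm_p, ], K[perm_k, ], 0.07), tolerance = 1e-12)
      for (v in c(info_nce_loss(q, kp, K, 0.07),
                  supcon_loss(q, P, K, 0.07),
                  self_margin_loss(q, kp, K, loss_params()),
                  additive_angular_margin_loss(q, K[1:4, ], 1, loss_params()))) {
        expect_true(is.finite(v) && v >= 0)
      }
    }
  })
})

test_that("the total pretraining loss is the plain sum of its components", {
  expect_equal(total_pretrain_loss(0.5, 0.3), 0.8)
  expect_equal(total_pretrain_loss(1.7, 0), 1.7)
  expect_error(total_pretrain_loss(Inf, 1), "finite")
  # linearity: batch mean of sums equals sum of batch means
  a <- c(0.2, 0.4, 0.9); b <- c(1.1, 0.3, 0.5)
  expect_equal(mean(mapply(total_pretrain_loss, a, b)),
               total_pretrain_loss(mean(a), mean(b)))
})
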