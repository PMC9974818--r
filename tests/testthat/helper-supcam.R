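# shared fixtures and independent oracles, built in code at test time

tiny_cfg <- function(canvas = 48, ...) synth_config(canvas_size = canvas, ...)

rand_unit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

rand_unit_rows <- function(n, d) t(replicate(n, rand_unit(d)))

# central finite differences of a scalar function of a vector
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# independent one-vs-rest metrics oracle (fractions, zero denominators -> 0)
oracle_macro_metrics <- function(truth, pred, classes) {
  per <- sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    c(prec, sens, spec, f1)
  })
  list(accuracy = mean(truth == pred),
       precision = mean(per[1, ]), sensitivity = mean(per[2, ]),
       specificity = mean(per[3, ]), f1 = mean(per[4, ]))
}

# a small pool of synthetic samples shared across expensive tests
local_sample_pool <- local({
  cache <- NULL
  function(n_each = 6, canvas = 48) {
    if (is.null(cache)) {
      cfg <- tiny_cfg(canvas)
      withr::with_seed(424242, {
        cache <<- unlist(lapply(cluster_labels(), function(l) {
          lapply(seq_len(n_each), function(i) {
            if (l == "instance") make_instance(cfg) else make_cluster(cfg, l)
          })
        }), recursive = FALSE)
      })
    }
    cache
  }
})
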