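# Dense brute-force propagator construction: textbook formulas, shared with
# nothing in the package.
bf_propagators <- function(adj) {
  n <- nrow(adj)
  At <- adj + diag(n)
  D <- diag(rowSums(At))
  list(A = adj,
       A2 = adj %*% adj,
       RW = solve(D) %*% At,
       SYM = solve(sqrt(D)) %*% At %*% solve(sqrt(D)))
}

test_that("propagators match dense brute-force products on all fixtures", {
  fixtures <- lapply(fixture_graphs(), function(am) {
    sg <- extract_enclosing_subgraph(am, 1, 1, label = 0, h = 3)
    sg$adj
  })
  fixtures$single_edge <- rbind(c(0, 1), c(1, 0))
  fixtures$empty <- matrix(0, 3, 3)
  for (nm in names(fixtures)) {
    adj <- fixtures[[nm]]
    got <- build_propagators(adj)
    want <- bf_propagators(adj)
    for (p in names(want)) {
      expect_equal(unname(got[[p]]), unname(want[[p]]), tolerance = 1e-6,
                   label = paste(nm, p))
    }
  }
  # empty adjacency: RAW_A = 0, RW = I (self-loops only)
  got <- build_propagators(matrix(0, 4, 4))
  expect_equal(got$A, matrix(0, 4, 4))
  expect_equal(got$RW, diag(4))
})

test_that("A^2 carries homogeneous-side common-neighbor counts only", {
  # single edge: each endpoint reaches itself through its neighbor
  expect_equal(build_propagators(rbind(c(0, 1), c(1, 0)), "A2")$A2, diag(2))

  # star d1 with m1..m5: every miRNA pair shares exactly 1 common neighbor
  star_adj <- matrix(0, 6, 6)
  star_adj[1:5, 6] <- star_adj[6, 1:5] <- 1
  A2 <- build_propagators(star_adj, "A2")$A2
  expect_true(all(A2[1:5, 1:5][upper.tri(diag(5))] == 1))
  expect_equal(diag(A2)[6], 5)

  for (seed in 1:8) {
    am <- random_bipartite(8, 7, 0.35, seed = 60 + seed)
    sg <- extract_enclosing_subgraph(am, 1, 1, label = 0, h = 2)
    A2 <- build_propagators(sg$adj, "A2")$A2
    cross <- outer(sg$side, sg$side, "!=")
    expect_true(all(A2[cross] == 0))
    # same-side entries count common neighbors
    n <- nrow(sg$adj)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sg$side[i] == sg$side[j]) {
        expect_equal(A2[i, j], sum(sg$adj[i, ] * sg$adj[j, ]))
      }
    }
  }
})

test_that("a single-propagator layer with identity weight reduces to f(A) %*% X", {
  adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))  # 3-node path
  X <- diag(3)
  props <- build_propagators(adj, "A")
  Z <- graph_conv_layer(X, props, diag(3), activation = identity)
  expect_equal(Z, adj %*% X)

  # all-zero input propagates to activation(0)
  Z0 <- graph_conv_layer(matrix(0, 3, 3), props, diag(3))
  expect_true(all(Z0 == 0))

  # spliced multi-propagator concat matches the dense oracle
  props4 <- build_propagators(adj)
  W <- with_seed(3, matrix(rnorm(12 * 2), 12, 2))
  Z4 <- graph_conv_layer(X, props4, W, activation = identity)
  H <- cbind(adj %*% X, (adj %*% adj) %*% X,
             bf_propagators(adj)$RW %*% X, bf_propagators(adj)$SYM %*% X)
  expect_equal(Z4, H %*% W, tolerance = 1e-6)

  expect_error(graph_conv_layer(X, props4, matrix(0, 5, 2)), "mismatch")
})

test_that("stacked layers concatenate per-layer outputs and preserve node count", {
  adj <- with_seed(8, {
    B <- matrix(rbinom(20, 1, 0.4), 5, 4)
    rbind(cbind(matrix(0, 5, 5), B), cbind(t(B), matrix(0, 4, 4)))
  })
  X <- build_features(rep(1, 9), label_encoding(3))
  props <- build_propagators(adj)
  W1 <- with_seed(1, matrix(rnorm(4 * 5 * 3), 20, 3))
  W2 <- with_seed(2, matrix(rnorm(4 * 3 * 1), 12, 1))
  Zcat <- stack_conv_layers(X, props, list(W1, W2))
  expect_equal(dim(Zcat), c(9L, 4L))
  Z1 <- graph_conv_layer(X, props, W1)
  expect_equal(Zcat[, 1:3], Z1)
  expect_equal(Zcat[, 4, drop = FALSE], graph_conv_layer(Z1, props, W2))
  # T = 1 reduces to a single layer
  expect_equal(stack_conv_layers(X, props, list(W1)), Z1)
})

test_that("sort pooling orders lexicographically from the last channel and pads", {
  Z <- rbind(c(5, 1), c(0, 3), c(9, 3))
  # last channel descending: rows 2,3 (tie 3) then row 1; tie broken by
  # penultimate channel: row 3 (9) before row 2 (0)
  expect_equal(sort_pooling(Z, 3), rbind(c(9, 3), c(0, 3), c(5, 1)))
  # top-k truncation
  expect_equal(sort_pooling(Z, 1), rbind(c(9, 3)))
  # padding with zero rows
  P <- sort_pooling(Z[1:2, ], 5)
  expect_equal(dim(P), c(5L, 2L))
  expect_equal(P[3:5, ], matrix(0, 3, 2))
  # n = k is a pure reordering
  expect_equal(sort(sort_pooling(Z, 3)), sort(Z))
  # identical rows: output invariant to which is "first"
  Zt <- rbind(c(1, 2), c(1, 2))
  expect_equal(sort_pooling(Zt, 2), Zt)
})

test_that("the read-out head emits a valid 2-class log-softmax", {
  cfg <- model_config(conv_dims = c(4, 4, 1), pooling_k = 12, seed = 3)
  params <- init_params(cfg, L = 6, k = 12)
  pooled <- with_seed(5, matrix(rnorm(12 * 9), 12, 9))
  lp <- conv1d_head(pooled, params, cfg)
  expect_length(lp, 2)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-6)
  # all-zero pooled input stays finite
  lp0 <- conv1d_head(matrix(0, 12, 9), params, cfg)
  expect_true(all(is.finite(lp0)))
  # k below the receptive field is a configuration error
  expect_error(init_params(cfg, L = 6, k = 4), "receptive field")
})

test_that("forward scores are probabilities, deterministic and permutation-invariant", {
  am <- random_bipartite(12, 10, 0.35, seed = 9)
  s <- balanced_samples(am, seed = 2)
  sgs <- batch_extract(am, s[c(1:5, (sum(s$label) + 1):(sum(s$label) + 5)), ],
                       h = 2, label_encoding(10))
  cfg <- model_config(conv_dims = c(6, 6, 1), pooling_k = 10, seed = 4)
  m <- train(sgs, cfg, train_spec(epochs = 3, batch_size = 5, seed = 1))
  for (sg in sgs[1:4]) {
    p <- forward(sg, m)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(forward(sg, m), p)  # identical inputs, identical outputs
    n <- nrow(sg$adj)
    if (n > 3) {
      perm <- c(1, 2, with_seed(n, sample(3:n)))
      sgp <- sg
      sgp$adj <- sg$adj[perm, perm]
      sgp$labels <- sg$labels[perm]
      sgp$features <- sg$features[perm, ]
      sgp$side <- sg$side[perm]
      sgp$global <- sg$global[perm]
      expect_equal(forward(sgp, m), p, tolerance = 1e-5)
    }
  }
  # compiled path equals the dense reference path
  expect_equal(predict_subgraphs(m, sgs),
               vapply(sgs, forward, numeric(1), model = m),
               tolerance = 1e-6)
  # feature-width mismatch is caught
  sgs_wide <- batch_extract(am, s[1:2, ], h = 2, label_encoding(20))
  expect_error(predict_subgraphs(m, sgs_wide), "width")
})

test_that("nll_loss satisfies its closed-form contracts", {
  # perfect prediction: log-prob 0 at the truth
  expect_equal(nll_loss(rbind(c(-Inf, 0), c(0, -Inf)), c(1, 0)), 0)
  # uniform predictor: ln 2
  lp <- matrix(log(0.5), 4, 2)
  expect_equal(nll_loss(lp, c(0, 1, 1, 0)), log(2), tolerance = 1e-9)
  # permutation invariance over the batch
  set.seed(31)
  p1 <- runif(6)
  lp6 <- cbind(log(1 - p1), log(p1))
  y <- rep(0:1, 3)
  perm <- sample(6)
  expect_equal(nll_loss(lp6, y), nll_loss(lp6[perm, ], y[perm]))
})

test_that("analytic gradients match finite differences at a generic point", {
  am <- random_bipartite(6, 5, 0.3, seed = 21)
  s <- balanced_samples(am, seed = 3)
  sgs <- batch_extract(am, s[c(1, 2, nrow(s) - 1, nrow(s)), ], h = 1,
                       label_encoding(8))
  cfg <- model_config(conv_dims = c(3, 1), pooling_k = 10, seed = 6)
  m <- untrained_model(sgs, cfg)
  # move off the all-zero biases so no ReLU sits exactly at its kink
  m$params <- with_seed(17, lapply(m$params, function(p) {
    if (is.list(p)) lapply(p, function(w) w + matrix(rnorm(length(w), sd = 0.05),
                                                     nrow(w)))
    else p + rnorm(length(p), sd = 0.05)
  }))
  lg <- loss_gradients(m, sgs)
  eps <- 1e-6
  for (nm in c("K1", "K2", "Wd1", "Wd2", "b1", "bd2")) {
    p <- m$params[[nm]]
    for (i in with_seed(50 + nchar(nm), sample(length(p), 2))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm <- m; mm$params[[nm]][i] <- p[i] - eps
      fd <- (loss_gradients(mp, sgs)$loss - loss_gradients(mm, sgs)$loss) /
        (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
    }
  }
  for (t in 1:2) {
    p <- m$params$W[[t]]
    for (i in with_seed(60 + t, sample(length(p), 2))) {
      mp <- m; mp$params$W[[t]][i] <- p[i] + eps
      mm <- m; mm$params$W[[t]][i] <- p[i] - eps
      fd <- (loss_gradients(mp, sgs)$loss - loss_gradients(mm, sgs)$loss) /
        (2 * eps)
      an <- lg$grads$W[[t]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
    }
  }
})

test_that("ablation variants and the baseline all build and train cleanly", {
  am <- random_bipartite(14, 12, 0.35, seed = 33)
  s <- balanced_samples(am, seed = 4)
  keep <- c(1:8, (sum(s$label) + 1):(sum(s$label) + 8))
  sgs <- batch_extract(am, s[keep, ], h = 1, label_encoding(10))
  for (v in names(ablation_variants())) {
    cfg <- ablation_variants(model_config(conv_dims = c(4, 4, 1),
                                          pooling_k = 10, seed = 2))[[v]]
    m <- train(sgs, cfg, train_spec(epochs = 2, batch_size = 8, seed = 3))
    sc <- predict_subgraphs(m, sgs)
    expect_true(all(is.finite(sc)))
    expect_true(all(sc >= 0 & sc <= 1))
  }
  expect_equal(ablation_variants()$a$propagators, c("A2", "RW", "SYM"))
  expect_equal(ablation_variants()$b$propagators, c("A", "RW", "SYM"))
  expect_equal(ablation_variants()$c$propagators, c("A", "A2", "SYM"))
  expect_equal(ablation_variants()$d$propagators, c("A", "A2", "RW"))
  expect_equal(ablation_variants()$baseline$propagators, "SYM")
})

test_that("model configuration validates its invariants and round-trips via YAML", {
  expect_error(model_config(propagators = character(0)), "at least one")
  expect_error(model_config(conv_dims = c(8, 2)), "width 1")
  expect_error(model_config(pooling_k = 0), "positive")
  cfg <- model_config(propagators = c("A", "SYM"), conv_dims = c(16, 1),
                      pooling_k = 25, seed = 12)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  expect_equal(read_model_config(f), cfg)
})

test_that("checkpoints round-trip parameters at full precision", {
  am <- random_bipartite(10, 8, 0.4, seed = 13)
  s <- balanced_samples(am, seed = 5)
  keep <- c(1:5, (sum(s$label) + 1):(sum(s$label) + 5))
  sgs <- batch_extract(am, s[keep, ], h = 1, label_encoding(8))
  m <- train(sgs, model_config(conv_dims = c(4, 1), pooling_k = 10, seed = 9),
             train_spec(epochs = 2, batch_size = 5, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict_subgraphs(m2, sgs), predict_subgraphs(m, sgs))
  expect_equal(m2$resolved_k, m$resolved_k)
  expect_equal(m2$config$propagators, m$config$propagators)
})
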