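random_layer_params <- function(heads, ds, din, seed = 1) {
  set.seed(seed)
  lapply(seq_len(heads), function(k) {
    list(W = matrix(rnorm(ds * din, sd = 0.3), ds, din),
         a = rnorm(2 * ds, sd = 0.3))
  })
}

test_that("attention layer matches a per-edge loop oracle", {
  set.seed(11)
  n <- 5L; din <- 4L; ds <- 3L
  h <- matrix(rnorm(n * din), n)
  adj <- ring_graph(n)
  lp <- random_layer_params(2L, ds, din, seed = 2)
  out <- gat_layer_forward(h, adj, lp, slope = 0.2)
  # oracle: explicit loops over nodes and inclusive neighborhoods
  oracle <- NULL
  for (k in 1:2) {
    W <- lp[[k]]$W; a <- lp[[k]]$a
    ok <- matrix(0, n, ds)
    for (i in 1:n) {
      nb <- sort(unique(c(i, which(adj[i, ] > 0))))
      e <- sapply(nb, function(j) {
        v <- c(W %*% h[i, ], W %*% h[j, ])
        s <- sum(a * v)
        if (s > 0) s else 0.2 * s
      })
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      agg <- rep(0, ds)
      for (t in seq_along(nb)) agg <- agg + alpha[t] * (W %*% h[nb[t], ])
      ok[i, ] <- ifelse(agg > 0, agg, exp(agg) - 1)  # ELU
    }
    oracle <- cbind(oracle, ok)
  }
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("attention coefficients sum to one over each neighborhood", {
  set.seed(12)
  n <- 8L
  h <- matrix(rnorm(n * 5), n)
  adj <- ring_graph(n)
  res <- gat_layer_forward(h, adj, random_layer_params(3L, 4L, 5L),
                           want_cache = TRUE)
  for (alpha in res$alpha) {
    expect_equal(rowSums(alpha), rep(1, n), tolerance = 1e-6)
  }
})

test_that("an isolated node attends only to itself", {
  set.seed(13)
  n <- 4L
  h <- matrix(rnorm(n * 3), n)
  adj <- matrix(0, n, n)
  adj[1, 2] <- adj[2, 1] <- 1  # nodes 3 and 4 isolated
  lp <- random_layer_params(1L, 2L, 3L)
  res <- gat_layer_forward(h, adj, lp, want_cache = TRUE)
  expect_equal(res$alpha[[1]][3, 3], 1)
  expect_equal(sum(res$alpha[[1]][3, -3]), 0)
  expected <- elu(drop(lp[[1]]$W %*% h[3, ]))
  expect_equal(unname(res$out[3, ]), expected, tolerance = 1e-12)
})

test_that("the default encoder emits 16-dimensional embeddings", {
  set.seed(14)
  n <- 30L
  x <- matrix(rnorm(n * 166), n)
  adj <- ring_graph(n)
  model <- init_gaae(encoder_config(), decoder_config(), 166L, seed = 0)
  z <- encode(x, adj, model)
  expect_equal(dim(z), c(n, 16L))
  # determinism: same parameters, same input
  expect_identical(z, encode(x, adj, model))
  # zero latent projection collapses the embedding
  model$params[["mu.W"]][] <- 0
  model$params[["mu.b"]][] <- 0
  expect_true(all(encode(x, adj, model) == 0))
})

test_that("feature decoder matches hand computation on a toy", {
  enc <- encoder_config(layer_dims = 4L, heads = 1L, latent_dim = 2L)
  dec <- decoder_config(hidden_dims = 3L, leaky_slope = 0.1)
  model <- init_gaae(enc, dec, n_features = 2L, seed = 1)
  # zero weights -> zero output
  zero <- model
  for (nm in c("d1.W", "d1.b", "d1.ln.b", "dout.W", "dout.b")) {
    zero$params[[nm]][] <- 0
  }
  expect_true(all(decode_features(matrix(1:2, 1), zero) == 0))
  # hand-set weights, one subject
  model$params[["d1.W"]] <- matrix(c(1, 0, -1, 2, 1, 1), 3, 2)
  model$params[["d1.b"]] <- c(0.5, 0, -0.5)
  model$params[["d1.ln.g"]] <- c(1, 2, 1)
  model$params[["d1.ln.b"]] <- c(0, 0.1, 0)
  model$params[["dout.W"]] <- matrix(c(1, -1, 0.5, 0, 2, 1), 2, 3)
  model$params[["dout.b"]] <- c(0.1, -0.2)
  z <- matrix(c(0.3, -0.7), 1)
  u <- drop(model$params[["d1.W"]] %*% z[1, ] + model$params[["d1.b"]])
  xn <- (u - mean(u)) / sqrt(mean((u - mean(u))^2) + 1e-5)
  p <- c(1, 2, 1) * xn + c(0, 0.1, 0)
  hsub <- ifelse(p > 0, p, 0.1 * p)
  expected <- drop(model$params[["dout.W"]] %*% hsub +
                     model$params[["dout.b"]])
  expect_equal(drop(decode_features(z, model)), expected, tolerance = 1e-12)
  # output width always matches the feature count
  z5 <- matrix(rnorm(10), 5)
  expect_equal(dim(decode_features(z5, model)), c(5L, 2L))
})

test_that("structure decoder is the sigmoid of the embedding Gram matrix", {
  expect_true(all(decode_structure(matrix(0, 4, 3)) == 0.5))
  set.seed(15)
  z <- matrix(rnorm(6), 3, 2)
  ahat <- decode_structure(z)
  expect_lt(max(abs(ahat - t(ahat))), 1e-12)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ahat[i, j], 1 / (1 + exp(-sum(z[i, ] * z[j, ]))),
                 tolerance = 1e-12)
  }
})

test_that("loss identities hold and BCE matches a term-by-term oracle", {
  set.seed(16)
  x <- matrix(rnorm(12), 3, 4)
  adj <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  ahat <- matrix(runif(9, 0.1, 0.9), 3, 3)
  ahat <- (ahat + t(ahat)) / 2
  # perfect reconstruction
  expect_equal(compute_loss(x, x, adj, ahat, 0.5)$l_recon, 0)
  # lambda = 0 removes the structural term from the total
  xh <- x + rnorm(12, sd = 0.1)
  l0 <- compute_loss(x, xh, adj, ahat, 0)
  expect_equal(l0$l_total, l0$l_recon)
  # 2-node toy BCE oracle
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  p2 <- matrix(c(0.3, 0.8, 0.8, 0.4), 2, 2)
  manual <- -(log(1 - 0.3) + log(0.8) + log(0.8) + log(1 - 0.4)) / 4
  l2 <- compute_loss(matrix(0, 2, 2), matrix(0, 2, 2), a2, p2, 1)
  expect_equal(l2$l_struct, manual, tolerance = 1e-12)
  expect_error(compute_loss(x, xh, adj, ahat, -0.1), "lambda")
})

test_that("total loss is affine in lambda with slope l_struct", {
  set.seed(17)
  n <- 10L
  x <- matrix(rnorm(n * 6), n)
  adj <- ring_graph(n)
  model <- init_gaae(encoder_config(layer_dims = c(5L, 4L),
                                    heads = c(2L, 1L), latent_dim = 3L),
                     decoder_config(hidden_dims = 4L), 6L, seed = 3)
  z <- encode(x, adj, model)
  xh <- decode_features(z, model)
  ahat <- decode_structure(z)
  ls <- vapply(c(0, 0.5, 1),
               function(l) compute_loss(x, xh, adj, ahat, l)$l_total,
               numeric(1))
  slope <- compute_loss(x, xh, adj, ahat, 1)$l_struct
  expect_equal(ls[2] - ls[1], 0.5 * slope, tolerance = 1e-12)
  expect_equal(ls[3] - ls[1], slope, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(18)
  n <- 7L; f <- 5L
  x <- matrix(rnorm(n * f), n)
  adj <- ring_graph(n)
  enc <- encoder_config(layer_dims = c(4L, 3L), heads = c(2L, 1L),
                        latent_dim = 2L)
  dec <- decoder_config(hidden_dims = c(3L, 4L))
  model <- init_gaae(enc, dec, f, seed = 9)
  lam <- 0.7
  loss_fn <- function(m) {
    z <- encode(x, adj, m)
    compute_loss(x, decode_features(z, m), adj, decode_structure(z),
                 lam)$l_total
  }
  step <- pgsubtype:::gaae_step(model, x, adj, lam)
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(3L, length(p)))
    for (i in idx) {
      up <- model; up$params[[nm]][i] <- p[i] + eps
      dn <- model; dn$params[[nm]][i] <- p[i] - eps
      fd <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      an <- step$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("training is seed-deterministic and reduces the loss", {
  cohort <- generate_cohort(cohort_spec(n_id = 30L, n_hc = 3L, n_roi = 20L,
                                        n_skeleton = 25L, n_blocks = 4L,
                                        subtype_fractions = c(0.5, 0.5),
                                        seed = 19))
  graph <- build_population_graph(cohort, sparsity = 0.2)
  cfg <- train_config(epochs = 200L, lambda_struct = 0.3, seed = 7)
  fit1 <- train_gaae(graph, small_enc(), small_dec(), cfg)
  fit2 <- train_gaae(graph, small_enc(), small_dec(), cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$z, fit2$z)
  expect_lt(tail(fit1$loss_history$l_total, 1),
            fit1$loss_history$l_total[1])
  # attention normalization holds after training on every layer and head
  n <- nrow(graph$adjacency)
  for (layer in fit1$attention) {
    for (alpha in layer) {
      expect_equal(unname(rowSums(alpha)), rep(1, n), tolerance = 1e-6)
    }
  }
})

test_that("training refuses an empty graph", {
  suppressWarnings({
    n <- 6L
    w <- matrix(0.5, n, n)
    graph <- build_adjacency(
      structure(list(s_i = w, c_d = matrix(0, n, n)),
                class = "similarity_matrices"),
      matrix(rnorm(n * 4), n))
  })
  expect_error(train_gaae(graph), "empty")
})

test_that("embeddings preserve planted-subtype recoverability", {
  # non-degradation: embedding clustering should track raw-feature
  # clustering on a strongly planted cohort (10-seed medians)
  raw <- numeric(10); emb <- numeric(10)
  for (s in 1:10) {
    cohort <- generate_cohort(small_spec(seed = 20 + s))
    graph <- build_population_graph(cohort)
    truth <- graph$pheno$true_subtype
    raw[s] <- adjusted_rand_index(
      cluster_latent(scale(graph$node_features), 2, seed = s), truth)
    fit <- train_gaae(graph, small_enc(), small_dec(),
                      train_config(epochs = 150L, lambda_struct = 0.3,
                                   seed = s))
    emb[s] <- adjusted_rand_index(cluster_latent(fit$z, 2, seed = s), truth)
  }
  expect_gte(median(emb), median(raw) - 0.05)
})
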