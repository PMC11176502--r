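test_that("adjacency normalisation matches the symmetric degree scaling", {
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(a), a)   # both degrees 1

  expect_equal(normalize_adjacency(matrix(0, 3, 3)), matrix(0, 3, 3))

  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")

  # spectral radius never exceeds 1
  set.seed(21)
  for (i in 1:10) {
    a <- matrix(rbinom(100, 1, 0.3), 10)
    a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
    ev <- eigen(normalize_adjacency(a), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-8)
  }
})

test_that("plain GCN layer is an activated projection of propagated features", {
  x <- matrix(abs(rnorm(12)), 4)
  expect_equal(gcn_layer(x, diag(4), diag(3)), x)  # identity pass-through
  expect_equal(gcn_layer(matrix(0, 4, 3), diag(4), diag(3)), matrix(0, 4, 3))

  set.seed(5)
  a <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3)
  an <- normalize_adjacency(a)
  w <- matrix(rnorm(6), 3, 2)
  got <- gcn_layer(x[1:3, ], an, w)
  ref <- an %*% x[1:3, ] %*% w
  ref <- ifelse(ref >= 0, ref, 0.01 * ref)
  expect_equal(got, ref)
  expect_error(gcn_layer(x, diag(4), diag(2)), "mismatch")
})

test_that("collapsed propagation applies S^K then a row softmax", {
  set.seed(6)
  x <- matrix(rnorm(12), 6, 2)
  # identity graph: softmax of the projected features
  out <- mgc_propagate(x, diag(6), diag(2), 1)
  expect_equal(out, exp(x) / rowSums(exp(x)))
  expect_equal(unname(rowSums(out)), rep(1, 6))

  # K = 2 on a path graph equals step-by-step propagation
  path <- matrix(0, 6, 6)
  for (i in 1:5) path[i, i + 1] <- path[i + 1, i] <- 1
  s <- normalize_adjacency(path)
  m <- matrix(rnorm(4), 2, 2)
  step <- s %*% (s %*% x)          # independent two-step oracle
  expect_equal(mgc_propagate(x, s, m, 2),
               exp(step %*% m - apply(step %*% m, 1, max)) /
                 rowSums(exp(step %*% m - apply(step %*% m, 1, max))))
  expect_error(mgc_propagate(x, s, m, 0), "steps")
})

test_that("encoding matches a dense-algebra oracle and is seeded", {
  set.seed(30)
  a <- matrix(rbinom(25, 1, 0.4), 5); a <- 1 * ((a + t(a)) > 0); diag(a) <- 1
  x <- matrix(runif(20), 5, 4)
  cfg <- encoder_config(hidden_dim = 3L, latent_dim = 2L, seed = 9)
  w <- init_encoder_weights(4L, cfg)
  an <- normalize_adjacency(a)
  emb <- vgae_encode(x, an, w, cfg)

  px <- an %*% (an %*% x)
  u <- px %*% w$m_mgc
  h <- exp(u - apply(u, 1, max)) / rowSums(exp(u - apply(u, 1, max)))
  expect_equal(emb$mu, an %*% h %*% w$w_mu)
  expect_equal(emb$log_var, an %*% h %*% w$w_sigma)
  expect_equal(emb$z, emb$mu)

  # zero weights give zero latent parameters
  w0 <- w; w0$w_mu[] <- 0; w0$w_sigma[] <- 0
  emb0 <- vgae_encode(x, an, w0, cfg)
  expect_true(all(emb0$mu == 0) && all(emb0$log_var == 0))

  # weight init is reproducible from the seed
  expect_identical(init_encoder_weights(4L, cfg), w)
})

test_that("reparameterization recovers the mean and scales the noise", {
  mu <- matrix(1:6 / 10, 2, 3)
  lv <- matrix(0, 2, 3)
  expect_equal(reparameterize(mu, lv, noise = matrix(0, 2, 3)), mu)
  expect_equal(reparameterize(mu, lv, noise = matrix(1, 2, 3)), mu + 1)

  set.seed(40)
  draws <- replicate(10000, reparameterize(matrix(0.3), matrix(log(0.25))))
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
})

test_that("inner-product decoder is symmetric, bounded and logistic", {
  expect_equal(vgae_decode(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  set.seed(41)
  z <- matrix(rnorm(8), 4, 2)
  p <- vgae_decode(z)
  expect_equal(p, t(p))
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, 1 / (1 + exp(-z %*% t(z))))  # element-wise oracle
  # scaling saturates probabilities away from 0.5
  p_big <- vgae_decode(10 * z)
  expect_true(all(abs(p_big - 0.5) >= abs(p - 0.5) - 1e-12))
})

test_that("loss combines weighted reconstruction error and KL divergence", {
  mu0 <- matrix(0, 3, 2); lv0 <- matrix(0, 3, 2)
  a <- diag(3)
  l <- vgae_loss(matrix(0.5, 3, 3), a, mu0, lv0)
  expect_equal(l$kl, 0)

  # perfect reconstruction drives the BCE term to zero
  d <- 1e-9
  p_perfect <- ifelse(a == 1, 1 - d, d)
  expect_lt(vgae_loss(p_perfect, a, mu0, lv0)$recon, 1e-6)

  # closed-form oracle on a random case
  set.seed(42)
  p <- matrix(runif(9, 0.05, 0.95), 3)
  mu <- matrix(rnorm(6), 3); lv <- matrix(rnorm(6, sd = 0.3), 3)
  got <- vgae_loss(p, a, mu, lv)
  w_pos <- (9 - 3) / 3
  recon_ref <- -sum(w_pos * a * log(p) + (1 - a) * log(1 - p)) / 9
  kl_ref <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / 3
  expect_equal(got$recon, recon_ref)
  expect_equal(got$kl, kl_ref)
  expect_equal(got$loss, recon_ref + kl_ref)

  # KL is non-negative for any Gaussian parameters
  set.seed(43)
  kls <- replicate(1000, {
    vgae_loss(matrix(0.5, 1, 1), matrix(1, 1, 1),
              matrix(rnorm(4), 1), matrix(rnorm(4, sd = 2), 1))$kl
  })
  expect_true(all(kls >= 0))
})

test_that("training reduces the loss and respects the epoch budget", {
  syn <- tiny_dataset()
  params <- tiny_params()
  inp <- build_side_inputs(sequence_similarity_matrix(syn$sequences),
                           syn$associations, "microbe", params)

  ok <- vapply(1:20, function(s) {
    fit <- vgae_train(inp$graph, encoder_config(hidden_dim = 16L,
                                                latent_dim = 16L,
                                                epochs = 60L, seed = s))
    # per-epoch losses are stochastic (fresh latent noise each epoch), so
    # compare smoothed early/late averages of the training curve
    mean(tail(fit$loss_history, 10)) < mean(head(fit$loss_history, 10))
  }, logical(1))
  expect_gte(sum(ok), 18)

  # zero epochs returns the initial weights untouched
  cfg0 <- encoder_config(hidden_dim = 16L, latent_dim = 16L, epochs = 0L,
                         seed = 3)
  fit0 <- vgae_train(inp$graph, cfg0)
  expect_identical(fit0$weights, init_encoder_weights(ncol(inp$graph$features),
                                                      cfg0))
  expect_length(fit0$loss_history, 0)
})

test_that("training reconstruction improves over the initial decoder", {
  syn <- tiny_dataset()
  mss <- sequence_similarity_matrix(syn$sequences)
  gip <- gip_similarity(syn$associations$values,
                        syn$associations$microbe_ids)
  fused <- fuse_similarity(mss, gip)
  # a moderate threshold leaves a graph with genuine off-diagonal edges
  bin <- binarize_similarity(fused, 0.55)
  graph <- build_feature_graph(bin, fused, syn$associations, "microbe")
  an <- normalize_adjacency(graph$adjacency)
  cfg <- encoder_config(hidden_dim = 16L, latent_dim = 16L, epochs = 80L,
                        seed = 4)
  w_init <- init_encoder_weights(ncol(graph$features), cfg)
  fit <- vgae_train(graph, cfg)

  # standardise exactly as training does before re-encoding
  x <- graph$features
  csd <- apply(x, 2, sd); csd[csd < 1e-12] <- 1
  x <- scale(x, center = TRUE, scale = csd)
  rec_auc <- function(w) {
    p <- vgae_decode(vgae_encode(x, an, w, cfg)$mu)
    off <- row(p) != col(p)
    roc_auc(p[off], graph$adjacency[off])$auc
  }
  expect_gt(rec_auc(fit$weights), rec_auc(w_init))
})

test_that("default encoder dimensions follow the tuned configuration", {
  cfg <- encoder_config()
  expect_equal(cfg$hidden_dim, 128L)
  expect_equal(cfg$learning_rate, 0.01)
  expect_error(encoder_config(learning_rate = -1), "positive")
})
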