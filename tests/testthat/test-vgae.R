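test_that("zero encoder weights give mu = 0, log_var = 0 and Z = eps", {
  p <- vgae_init(4, hidden_dim = 3, latent_dim = 2, seed = 1)
  p$W0[] <- 0; p$W_mu[] <- 0; p$W_sigma[] <- 0
  X <- matrix(rnorm(20), 5, 4)
  A <- diag(5)
  eps <- matrix(rnorm(10), 5, 2)
  lat <- gcn_encode(X, A, p, eps = eps)
  expect_equal(lat$mu, matrix(0, 5, 2))
  expect_equal(lat$log_var, matrix(0, 5, 2))
  expect_equal(lat$Z, eps)
})

test_that("with a single self-looped spot the encoder is a plain 2-layer MLP", {
  p <- vgae_init(6, hidden_dim = 4, latent_dim = 3, seed = 2)
  x <- matrix(rnorm(6), 1, 6)
  lat <- gcn_encode(x, matrix(1, 1, 1), p, eps = matrix(0, 1, 3))
  h <- pmax(x %*% p$W0, 0)
  expect_equal(lat$mu, h %*% p$W_mu)
  expect_equal(lat$log_var, h %*% p$W_sigma)
})

test_that("permuting spots permutes the posterior means identically", {
  set.seed(9)
  X <- matrix(rnorm(8 * 5), 8, 5)
  A <- matrix(rbinom(64, 1, 0.4), 8, 8)
  A <- pmax(A, t(A)); diag(A) <- 0
  An <- normalize_adjacency(A)
  p <- vgae_init(5, hidden_dim = 4, latent_dim = 3, seed = 3)
  perm <- sample(8)
  mu1 <- gcn_encode(X, An, p, eps = matrix(0, 8, 3))$mu
  An_p <- normalize_adjacency(A[perm, perm])
  mu2 <- gcn_encode(X[perm, ], An_p, p, eps = matrix(0, 8, 3))$mu
  expect_equal(mu2, mu1[perm, ])
})

test_that("decoder outputs are symmetric, pointwise and 0.5 at Z = 0", {
  p <- vgae_init(7, hidden_dim = 4, latent_dim = 3, decoder_hidden = 5,
                 embed_dim = 2, seed = 4)
  p$ba0[] <- 0; p$ba1[] <- 0; p$bx0[] <- 0; p$bx1[] <- 0
  Z0 <- matrix(0, 4, 3)
  out <- vgae_decode(Z0, p)
  expect_true(all(abs(out$A_gen - 0.5) < 1e-12))
  Z <- matrix(rnorm(12), 4, 3)
  Z[2, ] <- Z[1, ]
  out2 <- vgae_decode(Z, p)
  expect_equal(out2$X_gen[1, ], out2$X_gen[2, ])    # pointwise decoder
  expect_equal(out2$A_gen, t(out2$A_gen))           # symmetry
  expect_true(all(out2$A_gen > 0 & out2$A_gen < 1))
})

test_that("loss terms match an independent scalar computation", {
  set.seed(11)
  n <- 3; m <- 4; d <- 2
  lat <- structure(list(mu = matrix(rnorm(n * d), n, d),
                        log_var = matrix(rnorm(n * d), n, d)),
                   class = "latent_representation")
  A_gen <- matrix(runif(n * n, 0.1, 0.9), n, n)
  A_gen <- (A_gen + t(A_gen)) / 2
  X_gen <- matrix(rnorm(n * m), n, m)
  outs <- structure(list(A_gen = A_gen, X_gen = X_gen),
                    class = "decoder_outputs")
  A_t <- matrix(rbinom(n * n, 1, 0.5), n, n); A_t <- pmax(A_t, t(A_t))
  X_t <- matrix(rnorm(n * m), n, m)
  w <- c(0.3, 1.7, 2.5)
  got <- vgae_loss(lat, outs, A_t, X_t, w)
  kl <- 0
  for (i in 1:n) for (k in 1:d)
    kl <- kl + 0.5 * (-lat$log_var[i, k] + lat$mu[i, k]^2 +
                        exp(lat$log_var[i, k]) - 1)
  bce <- 0
  for (i in 1:n) for (j in 1:n)
    bce <- bce - (A_t[i, j] * log(A_gen[i, j]) +
                    (1 - A_t[i, j]) * log(1 - A_gen[i, j]))
  bce <- bce / n
  mse <- mean((X_t - X_gen)^2)
  expect_equal(got$kl, kl)
  expect_equal(got$bce, bce)
  expect_equal(got$mse, mse)
  expect_equal(got$total, w[1] * kl + w[2] * bce + w[3] * mse)
  # trivial anchors
  lat0 <- structure(list(mu = matrix(0, n, d), log_var = matrix(0, n, d)),
                    class = "latent_representation")
  expect_equal(vgae_loss(lat0, outs, A_t, X_t, w)$kl, 0)
  outs2 <- structure(list(A_gen = A_gen, X_gen = X_t),
                     class = "decoder_outputs")
  expect_equal(vgae_loss(lat, outs2, A_t, X_t, w)$mse, 0)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(21)
  n <- 5; m <- 4
  X <- matrix(rnorm(n * m), n, m)
  A <- matrix(rbinom(n * n, 1, 0.5), n, n)
  A <- pmax(A, t(A)); diag(A) <- 0
  An <- normalize_adjacency(A)
  A_t <- (An != 0) * 1
  params <- vgae_init(m, hidden_dim = 3, latent_dim = 2, decoder_hidden = 3,
                      embed_dim = 2, seed = 5)
  eps <- matrix(rnorm(n * 2), n, 2)
  w <- c(0.5, 1, 1.5)
  P0 <- An %*% X
  loss_of <- function(pp) {
    fw <- spotcna:::.vgae_forward(pp, P0, An, eps)
    spotcna:::.vgae_loss_terms(fw, A_t, X, w, "binary", 2)$total
  }
  fw <- spotcna:::.vgae_forward(params, P0, An, eps)
  gr <- spotcna:::.vgae_backward(params, fw, P0, An, A_t, X, w, "binary", 2)
  h <- 1e-6
  for (nm in c("W0", "W_mu", "W_sigma", "Wa0", "Wa1", "ba1", "Wx0", "bx1")) {
    idx <- seq_len(min(3, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (loss_of(up) - loss_of(dn)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training is seed-deterministic and optimises its objective", {
  set.seed(31)
  sim <- blob_matrix(25, sep = 6, d = 8, seed = 31)
  coords <- cbind(x = rep(1:10, 5), y = rep(1:5, each = 10))
  g <- build_spot_graph(sim, coords, k = 5)
  f1 <- vgae_train(sim, g$A_norm, latent_dim = 4, hidden_dim = 8,
                   decoder_hidden = 8, embed_dim = 4, epochs = 40, seed = 2)
  f2 <- vgae_train(sim, g$A_norm, latent_dim = 4, hidden_dim = 8,
                   decoder_hidden = 8, embed_dim = 4, epochs = 40, seed = 2)
  expect_identical(f1$trace$total, f2$trace$total)
  expect_identical(f1$latent$mu, f2$latent$mu)
  # reconstruction improves over training
  expect_lt(f1$trace$mse[40], f1$trace$mse[1])
  # loss components always recombine into the total
  w <- f1$config$weights
  expect_equal(f1$trace$total,
               w[1] * f1$trace$kl + w[2] * f1$trace$bce + w[3] * f1$trace$mse,
               tolerance = 1e-6)
})

test_that("a KL-only objective drives the posterior toward the prior", {
  set.seed(41)
  X <- matrix(rnorm(30 * 6), 30, 6)
  coords <- cbind(x = rep(1:6, 5), y = rep(1:5, each = 6))
  g <- build_spot_graph(X, coords, k = 4)
  f <- vgae_train(X, g$A_norm, latent_dim = 3, hidden_dim = 6,
                  decoder_hidden = 4, embed_dim = 3, epochs = 400,
                  lambda1 = 1, lambda2 = 0, lambda3 = 0, seed = 3)
  expect_lt(f$trace$kl[400], 0.05 * f$trace$kl[1])
})

test_that("latent means separate clones better than permuted labels", {
  wins <- 0
  for (s in 1:10) {
    sim <- simulate_spatial_cna(simulation_config(
      grid = c(10, 10), n_clones = 1, n_chrom = 2, genes_per_arm = 50,
      seed = s))
    nm <- normalize_expression(sim$expr, min_genes_per_spot = 20,
                               min_spots_per_gene = 3)
    g <- build_spot_graph(nm$X, nm$coords, k = 8)
    f <- vgae_train(nm$X, g$A_norm, latent_dim = 8, hidden_dim = 16,
                    decoder_hidden = 16, embed_dim = 8, epochs = 80,
                    seed = s)
    lab <- sim$truth$clone[rownames(f$latent$mu)]
    d <- dist(f$latent$mu)
    sil_true <- mean(cluster::silhouette(as.integer(lab) + 1L, d)[, 3])
    set.seed(s + 100)
    sil_perm <- mean(cluster::silhouette(sample(as.integer(lab) + 1L), d)[, 3])
    if (sil_true > sil_perm) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("non-finite activations and divergence are reported as errors", {
  p <- vgae_init(3, hidden_dim = 2, latent_dim = 2, seed = 6)
  p$W0[] <- Inf
  X <- matrix(1, 2, 3)
  expect_error(gcn_encode(X, diag(2), p, eps = matrix(0, 2, 2)),
               "non-finite")
})
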