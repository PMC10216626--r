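# Multi-task variational graph autoencoder.
#
# Encoder: two graph-convolution propagation steps sharing the first-layer
# weights, with separate second-layer heads for the posterior mean and
# log-variance:
#   mu      = A~ ReLU(A~ X W0) W_mu
#   log s^2 = A~ ReLU(A~ X W0) W_sigma
#   Z       = mu + exp(log s^2 / 2) * eps,  eps ~ N(0, I)
# Decoders: two independent 2-layer ReLU MLPs; the adjacency head D1 maps Z
# to an embedding F whose inner products give edge logits, A_gen =
# sigmoid(F F'), symmetric by construction; the expression head D2 maps Z
# back to the gene space.
# Loss: lambda1 * KL(q(Z|X,A) || N(0,I)) + lambda2 * BCE(adjacency target,
# A_gen) + lambda3 * MSE(X, X_gen). Training is full batch with Adam and
# hand-derived gradients.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialise VGAE parameters
#'
#' Glorot-uniform weights (graph-convolution layers carry no biases; the
#' decoder MLPs do). The mu and sigma encoder heads share `W0` by
#' construction: it is stored once.
#'
#' @param n_genes Number of input genes (columns of X).
#' @param hidden_dim Encoder hidden width (default 128).
#' @param latent_dim Latent dimension d (default 32).
#' @param decoder_hidden Hidden width of both decoder MLPs (default 128).
#' @param embed_dim Output width of the adjacency decoder, i.e. the
#'   dimension in which edge logits are inner products (default 32).
#' @param seed RNG seed for the draw.
#' @return Named list of parameter matrices/vectors.
#' @export
vgae_init <- function(n_genes, hidden_dim = 128, latent_dim = 32,
                      decoder_hidden = 128, embed_dim = 32, seed = 1) {
  set.seed(seed)
  list(
    W0      = .glorot(n_genes, hidden_dim),
    W_mu    = .glorot(hidden_dim, latent_dim),
    W_sigma = .glorot(hidden_dim, latent_dim),
    Wa0 = .glorot(latent_dim, decoder_hidden), ba0 = numeric(decoder_hidden),
    Wa1 = .glorot(decoder_hidden, embed_dim),  ba1 = numeric(embed_dim),
    Wx0 = .glorot(latent_dim, decoder_hidden), bx0 = numeric(decoder_hidden),
    Wx1 = .glorot(decoder_hidden, n_genes),    bx1 = numeric(n_genes)
  )
}

#' Encode spots into the latent space
#'
#' Runs the two-step graph-convolutional encoder and draws a sampled
#' embedding by the reparameterization trick.
#'
#' @param X Spots x genes matrix.
#' @param A_norm Symmetrically normalized adjacency (dense, from
#'   [normalize_adjacency()]).
#' @param params Parameter list from [vgae_init()] (only the encoder
#'   entries are used).
#' @param eps Optional pre-drawn noise matrix (spots x latent); when
#'   `NULL` a draw is taken from the current RNG (seeded via `seed`).
#' @param seed Optional seed for the noise draw.
#' @return Object of class `latent_representation`: list with `mu`,
#'   `log_var`, `Z` and the recorded `eps`.
#' @export
gcn_encode <- function(X, A_norm, params, eps = NULL, seed = NULL) {
  X <- as.matrix(X); A_norm <- as.matrix(A_norm)
  U <- (A_norm %*% X) %*% params$W0
  H <- pmax(U, 0)
  Q <- A_norm %*% H
  mu <- Q %*% params$W_mu
  log_var <- Q %*% params$W_sigma
  if (!all(is.finite(mu)) || !all(is.finite(log_var)))
    stop("non-finite activations in the encoder")
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  Z <- mu + exp(log_var / 2) * eps
  structure(list(mu = mu, log_var = log_var, Z = Z, eps = eps),
            class = "latent_representation")
}

#' Decode latent representations
#'
#' Applies the two decoder MLPs: `A_gen = sigmoid(F F')` with `F` the
#' adjacency-head embedding (entries strictly inside (0, 1)), and `X_gen`
#' the reconstructed expression.
#'
#' @param Z Spots x latent matrix.
#' @param params Parameter list from [vgae_init()].
#' @return Object of class `decoder_outputs`: list with `A_gen`, `X_gen`
#'   and the embedding `F_a`.
#' @export
vgae_decode <- function(Z, params) {
  Z <- as.matrix(Z)
  Ha <- pmax(sweep(Z %*% params$Wa0, 2, params$ba0, "+"), 0)
  Fa <- sweep(Ha %*% params$Wa1, 2, params$ba1, "+")
  A_gen <- .clamp01(.sigmoid(tcrossprod(Fa)))
  Hx <- pmax(sweep(Z %*% params$Wx0, 2, params$bx0, "+"), 0)
  X_gen <- sweep(Hx %*% params$Wx1, 2, params$bx1, "+")
  structure(list(A_gen = A_gen, X_gen = X_gen, F_a = Fa),
            class = "decoder_outputs")
}

#' Multi-task VGAE loss
#'
#' Total loss `lambda1 * KL + lambda2 * BCE + lambda3 * MSE` with
#' `KL = (1/2) sum(-log s^2 + mu^2 + s^2 - 1)` over spots and dimensions,
#' the adjacency binary cross-entropy summed over all spot pairs and
#' divided by the number of spots, and the mean squared expression
#' reconstruction error. With `bce_target = "binary"` (default) the BCE
#' target is the binarized adjacency (edge present = 1, with optional
#' positive-class weighting); `"normalized"` keeps only the positive-class
#' term with the real-valued normalized adjacency as coefficient.
#'
#' @param latent A `latent_representation`.
#' @param outputs A `decoder_outputs`.
#' @param A_target Adjacency target matrix: 0/1 for `"binary"`,
#'   the normalized adjacency itself for `"normalized"`.
#' @param X_target Spots x genes expression target.
#' @param weights Numeric vector `c(lambda1, lambda2, lambda3)`,
#'   non-negative with at least one positive.
#' @param bce_target `"binary"` or `"normalized"`.
#' @param pos_weight Positive-class weight in the binary BCE (default 1).
#' @return List with `total`, `kl`, `bce`, `mse`.
#' @export
vgae_loss <- function(latent, outputs, A_target, X_target,
                      weights = c(1, 1, 1),
                      bce_target = c("binary", "normalized"),
                      pos_weight = 1) {
  bce_target <- match.arg(bce_target)
  stopifnot(length(weights) == 3, all(weights >= 0), any(weights > 0))
  n <- nrow(latent$mu)
  kl <- 0.5 * sum(-latent$log_var + latent$mu^2 + exp(latent$log_var) - 1)
  p <- .clamp01(outputs$A_gen)
  bce <- if (bce_target == "binary") {
    tt <- A_target
    -sum(pos_weight * tt * log(p) + (1 - tt) * log1p(-p)) / n
  } else {
    -sum(A_target * log(p)) / n
  }
  mse <- sum((X_target - outputs$X_gen)^2) / length(X_target)
  list(total = weights[1] * kl + weights[2] * bce + weights[3] * mse,
       kl = kl, bce = bce, mse = mse)
}

# full forward pass with caches for backprop; P0 = A_norm %*% X precomputed
.vgae_forward <- function(params, P0, A_norm, eps) {
  U <- P0 %*% params$W0
  H <- pmax(U, 0)
  Q <- A_norm %*% H
  mu <- Q %*% params$W_mu
  lv <- Q %*% params$W_sigma
  S <- exp(lv / 2)
  Z <- mu + S * eps
  Ua <- sweep(Z %*% params$Wa0, 2, params$ba0, "+")
  Ha <- pmax(Ua, 0)
  Fa <- sweep(Ha %*% params$Wa1, 2, params$ba1, "+")
  M <- tcrossprod(Fa)
  P <- .sigmoid(M)
  Ux <- sweep(Z %*% params$Wx0, 2, params$bx0, "+")
  Hx <- pmax(Ux, 0)
  Xg <- sweep(Hx %*% params$Wx1, 2, params$bx1, "+")
  list(U = U, H = H, Q = Q, mu = mu, lv = lv, S = S, Z = Z, Ua = Ua,
       Ha = Ha, Fa = Fa, P = P, Ux = Ux, Hx = Hx, Xg = Xg, eps = eps)
}

.vgae_loss_terms <- function(fw, A_target, X, weights, bce_target,
                             pos_weight) {
  n <- nrow(X)
  kl <- 0.5 * sum(-fw$lv + fw$mu^2 + exp(fw$lv) - 1)
  p <- .clamp01(fw$P)
  bce <- if (bce_target == "binary") {
    -sum(pos_weight * A_target * log(p) +
           (1 - A_target) * log1p(-p)) / n
  } else {
    -sum(A_target * log(p)) / n
  }
  mse <- sum((X - fw$Xg)^2) / length(X)
  list(total = weights[1] * kl + weights[2] * bce + weights[3] * mse,
       kl = kl, bce = bce, mse = mse)
}

.vgae_backward <- function(params, fw, P0, A_norm, A_target, X, weights,
                           bce_target, pos_weight) {
  n <- nrow(X)
  # expression head
  G_Xg <- weights[3] * 2 * (fw$Xg - X) / length(X)
  dWx1 <- crossprod(fw$Hx, G_Xg)
  dbx1 <- colSums(G_Xg)
  G_Hx <- tcrossprod(G_Xg, params$Wx1)
  G_Ux <- G_Hx * (fw$Ux > 0)
  dWx0 <- crossprod(fw$Z, G_Ux)
  dbx0 <- colSums(G_Ux)
  G_Z <- tcrossprod(G_Ux, params$Wx0)
  # adjacency head; G_M is symmetric because target and P are
  G_M <- if (bce_target == "binary") {
    (weights[2] / n) * ((1 - A_target) * fw$P -
                          pos_weight * A_target * (1 - fw$P))
  } else {
    -(weights[2] / n) * A_target * (1 - fw$P)
  }
  G_F <- 2 * (G_M %*% fw$Fa)
  dWa1 <- crossprod(fw$Ha, G_F)
  dba1 <- colSums(G_F)
  G_Ha <- tcrossprod(G_F, params$Wa1)
  G_Ua <- G_Ha * (fw$Ua > 0)
  dWa0 <- crossprod(fw$Z, G_Ua)
  dba0 <- colSums(G_Ua)
  G_Z <- G_Z + tcrossprod(G_Ua, params$Wa0)
  # reparameterization + KL
  G_mu <- G_Z + weights[1] * fw$mu
  G_lv <- 0.5 * G_Z * fw$eps * fw$S + weights[1] * 0.5 * (exp(fw$lv) - 1)
  dW_mu <- crossprod(fw$Q, G_mu)
  dW_sigma <- crossprod(fw$Q, G_lv)
  G_Q <- tcrossprod(G_mu, params$W_mu) + tcrossprod(G_lv, params$W_sigma)
  G_H <- A_norm %*% G_Q        # A_norm is symmetric
  G_U <- G_H * (fw$U > 0)
  dW0 <- crossprod(P0, G_U)
  list(W0 = dW0, W_mu = dW_mu, W_sigma = dW_sigma,
       Wa0 = dWa0, ba0 = dba0, Wa1 = dWa1, ba1 = dba1,
       Wx0 = dWx0, bx0 = dbx0, Wx1 = dWx1, bx1 = dbx1)
}

#' Train the multi-task VGAE
#'
#' Full-batch training with Adam. Deterministic given `seed`: the
#' parameter initialisation and the per-epoch reparameterization noise are
#' drawn from a seeded stream. The posterior mean `mu` (not a stochastic
#' `Z` sample) is what downstream clustering consumes.
#'
#' @param X Spots x genes normalized expression matrix.
#' @param A_norm Dense symmetrically normalized adjacency.
#' @param latent_dim,hidden_dim,decoder_hidden,embed_dim Architecture
#'   sizes (defaults 32/128/128/32).
#' @param epochs Training epochs (default 400).
#' @param lr Adam learning rate (default 1e-3).
#' @param lambda1 KL weight; `NULL` (default) sets `1/(n * latent_dim)`,
#'   which puts the KL term on the scale of the reconstruction terms.
#' @param lambda2,lambda3 Adjacency-BCE and expression-MSE weights
#'   (default 1 each).
#' @param bce_target `"binary"` (default) or `"normalized"`, see
#'   [vgae_loss()].
#' @param pos_weight Positive-class weight for the binary BCE; `NULL`
#'   (default) uses `(n^2 - |E|)/|E|` to balance sparse graphs.
#' @param seed RNG seed.
#' @param verbose Print the loss every 50 epochs.
#' @return Object of class `vgae_fit`: list with `params`, `latent` (final
#'   `latent_representation` under the trained parameters), `trace` (data
#'   frame epoch/kl/bce/mse/total) and the configuration used.
#' @export
vgae_train <- function(X, A_norm, latent_dim = 32, hidden_dim = 128,
                       decoder_hidden = 128, embed_dim = 32,
                       epochs = 400, lr = 1e-3, lambda1 = NULL,
                       lambda2 = 1, lambda3 = 1,
                       bce_target = c("binary", "normalized"),
                       pos_weight = NULL, seed = 1, verbose = FALSE) {
  bce_target <- match.arg(bce_target)
  X <- as.matrix(X); A_norm <- as.matrix(A_norm)
  n <- nrow(X); m <- ncol(X)
  if (is.null(lambda1)) lambda1 <- 1 / (n * latent_dim)
  weights <- c(lambda1, lambda2, lambda3)
  A_target <- if (bce_target == "binary") (A_norm != 0) * 1 else A_norm
  if (is.null(pos_weight)) {
    pos_weight <- if (bce_target == "binary") {
      ne <- sum(A_target)
      (n^2 - ne) / ne
    } else 1
  }
  set.seed(seed)
  params <- list(
    W0      = .glorot(m, hidden_dim),
    W_mu    = .glorot(hidden_dim, latent_dim),
    W_sigma = .glorot(hidden_dim, latent_dim),
    Wa0 = .glorot(latent_dim, decoder_hidden), ba0 = numeric(decoder_hidden),
    Wa1 = .glorot(decoder_hidden, embed_dim),  ba1 = numeric(embed_dim),
    Wx0 = .glorot(latent_dim, decoder_hidden), bx0 = numeric(decoder_hidden),
    Wx1 = .glorot(decoder_hidden, m),          bx1 = numeric(m)
  )
  P0 <- A_norm %*% X
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  trace <- matrix(NA_real_, epochs, 4,
                  dimnames = list(NULL, c("kl", "bce", "mse", "total")))
  for (ep in seq_len(epochs)) {
    eps <- matrix(rnorm(n * latent_dim), n, latent_dim)
    fw <- .vgae_forward(params, P0, A_norm, eps)
    lt <- .vgae_loss_terms(fw, A_target, X, weights, bce_target, pos_weight)
    trace[ep, ] <- c(lt$kl, lt$bce, lt$mse, lt$total)
    if (!is.finite(lt$total) || lt$total > 1e6)
      stop(sprintf("VGAE training diverged at epoch %d (loss %.4g; last values %s)",
                   ep, lt$total,
                   paste(signif(utils::tail(trace[, "total"][!is.na(trace[, "total"])], 5), 4),
                         collapse = ", ")))
    gr <- .vgae_backward(params, fw, P0, A_norm, A_target, X, weights,
                         bce_target, pos_weight)
    for (nm in names(gr)) {
      adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr[[nm]]
      adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- adam_m[[nm]] / (1 - b1^ep)
      vhat <- adam_v[[nm]] / (1 - b2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %4d  kl %.4g  bce %.4g  mse %.4g  total %.4g",
                      ep, lt$kl, lt$bce, lt$mse, lt$total))
  }
  latent <- gcn_encode(X, A_norm, params,
                       eps = matrix(rnorm(n * latent_dim), n, latent_dim))
  rownames(latent$mu) <- rownames(X)
  structure(
    list(params = params, latent = latent,
         trace = data.frame(epoch = seq_len(epochs), trace),
         config = list(latent_dim = latent_dim, hidden_dim = hidden_dim,
                       decoder_hidden = decoder_hidden,
                       embed_dim = embed_dim, epochs = epochs, lr = lr,
                       weights = weights, bce_target = bce_target,
                       pos_weight = pos_weight, seed = seed)),
    class = "vgae_fit"
  )
}

#' @export
print.vgae_fit <- function(x, ...) {
  cat(sprintf("vgae_fit: %d spots -> %d latent dims, %d epochs, final loss %.4g\n",
              nrow(x$latent$mu), ncol(x$latent$mu), x$config$epochs,
              x$trace$total[nrow(x$trace)]))
  invisible(x)
}
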