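test_that("Viterbi equals exhaustive path enumeration on random instances", {
  set.seed(23)
  for (rep in 1:200) {
    L <- sample(2:8, 1)
    p <- random_hmm_params()
    x <- rnorm(L, mean = sample(p$mu, L, replace = TRUE), sd = 0.5)
    got <- viterbi(x, p)
    want <- oracle_viterbi_enum(x, p$transition, p$initial, p$mu, p$sigma)
    expect_equal(got$states + 2L, want$path)
    expect_equal(got$log_prob, want$log_prob, tolerance = 1e-10)
  }
})

test_that("Viterbi ties break toward the lower state and likelihood dominates", {
  # all states identical: every path has the same probability
  p <- hmm_params(matrix(1 / 3, 3, 3), rep(1 / 3, 3), c(0, 0, 0),
                  c(1, 1, 1))
  v <- viterbi(c(0.3, -0.2, 0.8), p)
  expect_equal(v$states, rep(-1L, 3))  # deletion = lowest state index
  # strong amplification regime with sticky transitions
  tm <- matrix(0.005, 3, 3); diag(tm) <- 0.99
  p2 <- hmm_params(tm, rep(1 / 3, 3), c(-0.6, 0, 0.6), rep(0.1, 3))
  v2 <- viterbi(rep(0.62, 10), p2)
  expect_equal(v2$states, rep(1L, 10))
})

test_that("one EM iteration matches hand-computed forward-backward updates", {
  p <- hmm_params(matrix(c(0.8, 0.15, 0.05,
                           0.1, 0.8, 0.1,
                           0.05, 0.15, 0.8), 3, 3, byrow = TRUE),
                  c(0.2, 0.5, 0.3), c(-1, 0, 1), c(0.5, 0.4, 0.6))
  x <- c(0.4, -0.3)
  # exact posteriors by enumerating all 9 two-step paths
  joint <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    joint[i, j] <- p$initial[i] * dnorm(x[1], p$mu[i], p$sigma[i]) *
      p$transition[i, j] * dnorm(x[2], p$mu[j], p$sigma[j])
  z <- sum(joint)
  g1 <- rowSums(joint) / z
  g2 <- colSums(joint) / z
  xi <- joint / z
  pi_new <- g1
  t_new <- xi / rowSums(xi)
  mu_new <- (g1 * x[1] + g2 * x[2]) / (g1 + g2)
  sg_new <- sqrt((g1 * x[1]^2 + g2 * x[2]^2) / (g1 + g2) - mu_new^2)
  ord <- order(mu_new)
  fit <- suppressMessages(baum_welch(list(x), init = p, max_iter = 1))
  expect_equal(fit$initial, pi_new[ord])
  expect_equal(fit$transition, t_new[ord, ord])
  expect_equal(fit$mu, mu_new[ord])
  expect_equal(fit$sigma, pmax(sg_new[ord], 1e-3))
  expect_equal(fit$loglik_trace, log(z))
})

test_that("Baum-Welch log-likelihood is non-decreasing on varied fixtures", {
  set.seed(24)
  fixtures <- list(
    lapply(1:5, function(i) rnorm(30)),                      # single Gaussian
    lapply(1:3, function(i) rnorm(40, rep(c(-1, 1), 20))),   # bimodal
    list(rep(0, 25) + rnorm(25, sd = 0.01))                  # near-constant
  )
  for (seqs in fixtures) {
    fit <- suppressMessages(baum_welch(seqs, max_iter = 40))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_true(all(abs(rowSums(fit$transition) - 1) < 1e-9))
    expect_true(!is.unsorted(fit$mu))
  }
})

test_that("forced 3-state fit of one Gaussian keeps means within range", {
  set.seed(25)
  seqs <- lapply(1:10, function(i) rnorm(50, mean = 2, sd = 0.3))
  fit <- suppressMessages(baum_welch(seqs, max_iter = 50))
  expect_true(all(fit$mu >= min(unlist(seqs)) & fit$mu <= max(unlist(seqs))))
})

test_that("parameters are recovered from simulated sequences", {
  tm <- matrix(0.025, 3, 3); diag(tm) <- 0.95
  truth <- hmm_params(tm, rep(1 / 3, 3), c(-0.6, 0, 0.6), rep(0.2, 3))
  sim <- simulate_hmm_sequences(truth, 200, 500, seed = 42)
  fit <- baum_welch(sim$sequences)
  expect_true(all(abs(fit$mu - truth$mu) <= 0.1))
  expect_true(all(abs(diag(fit$transition) - 0.95) <= 0.05))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # decoding accuracy against the generating paths
  acc <- mean(unlist(Map(function(s, p) (viterbi(s, fit)$states + 2) == p,
                         sim$sequences[1:20], sim$paths[1:20])))
  expect_gt(acc, 0.95)
})

test_that("invalid parameters and sequences are rejected", {
  expect_error(hmm_params(matrix(1, 3, 3), rep(1 / 3, 3), 1:3, rep(1, 3)),
               "sum to 1")
  expect_error(hmm_params(diag(3), c(0.5, 0.5, 0.5), 1:3, rep(1, 3)),
               "sum to 1")
  expect_error(hmm_params(diag(3), rep(1 / 3, 3), c(1, 0, -1), rep(1, 3)),
               "mu_del")
  expect_error(hmm_params(diag(3), rep(1 / 3, 3), 1:3, c(1, 0, 1)),
               "positive")
  expect_error(baum_welch(list(c(1))), "length >= 2")
})

test_that("the emission floor clamps collapsing variances with a message", {
  seqs <- list(rep(1, 50), rep(1, 50))
  expect_message(fit <- baum_welch(seqs, max_iter = 5), "clamped")
  expect_true(all(fit$sigma >= 1e-3))
})
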