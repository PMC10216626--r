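# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# per-position median over shrinking windows, via stats::median
oracle_median_filter <- function(s, window) {
  h <- (window - 1) / 2
  n <- length(s)
  vapply(seq_len(n), function(i)
    median(s[max(1, i - h):min(n, i + h)]), numeric(1))
}

# exhaustive Viterbi: enumerate all 3^L state paths; first strict maximum
# in lexicographic order (matches lowest-state-index tie-breaking)
oracle_viterbi_enum <- function(x, transition, initial, mu, sigma) {
  L <- length(x)
  grid <- as.matrix(expand.grid(rev(replicate(L, 1:3, simplify = FALSE))))
  grid <- grid[, rev(seq_len(L)), drop = FALSE]  # lexicographic order
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    lp <- log(initial[p[1]]) + sum(dnorm(x, mu[p], sigma[p], log = TRUE))
    if (L > 1)
      lp <- lp + sum(log(transition[cbind(p[-L], p[-1])]))
    if (lp > best) {
      best <- lp
      best_path <- p
    }
  }
  list(path = unname(best_path), log_prob = best)
}

# pair-counting adjusted Rand index over all C(n,2) item pairs
oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}

# brute-force Ripley K: explicit double loop over ordered pairs
oracle_ripley <- function(points, d_grid, n_domain) {
  n <- nrow(points)
  lambda <- n / n_domain
  vapply(d_grid, function(d) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt(sum((points[i, ] - points[j, ])^2)) <= d)
        cnt <- cnt + 1
    }
    cnt / (lambda * n)
  }, numeric(1))
}

# one-sided Fisher p-values by explicit hypergeometric tail enumeration
oracle_fisher_onesided <- function(n11, n10, n01, n00) {
  m <- n11 + n01          # total successes
  nn <- n10 + n00
  k <- n11 + n10          # draws (group A size)
  support <- max(0, k - nn):min(k, m)
  pmf <- vapply(support, function(x) dhyper(x, m, nn, k), numeric(1))
  list(greater = sum(pmf[support >= n11]),
       less = sum(pmf[support <= n11]))
}

# step-up Benjamini-Hochberg, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

random_hmm_params <- function() {
  tm <- matrix(runif(9, 0.05, 1), 3, 3)
  tm <- tm / rowSums(tm)
  pi0 <- runif(3, 0.05, 1); pi0 <- pi0 / sum(pi0)
  mu <- sort(rnorm(3, 0, 1))
  hmm_params(tm, pi0, mu, runif(3, 0.2, 1))
}
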