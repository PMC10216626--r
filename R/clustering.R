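#' Louvain clustering of latent representations
#'
#' Builds a union-symmetrized K-nearest-neighbour graph (unit edge
#' weights, Euclidean distance) over the latent posterior means and runs
#' Louvain modularity optimisation. Deterministic given `seed`.
#'
#' @param mu Spots x d latent matrix (posterior means from
#'   [vgae_train()]).
#' @param k_latent Neighbours for the latent KNN graph (default 15).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed (Louvain visits vertices in random order).
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (integer vector, contiguous from 0, named by spot when `mu` has row
#'   names), `modularity`, and the parameters used.
#' @export
louvain_cluster <- function(mu, k_latent = 15, resolution = 1, seed = 0) {
  mu <- as.matrix(mu)
  n <- nrow(mu)
  if (n < 3) stop("need at least 3 spots to cluster")
  if (k_latent >= n) stop("k_latent must be smaller than the number of spots")
  A <- knn_expression_graph(mu, k = k_latent, W1 = 1)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- rownames(mu)
  structure(
    list(labels = labels, modularity = max(cl$modularity),
         n_clusters = length(unique(labels)),
         params = list(k_latent = k_latent, resolution = resolution,
                       seed = seed)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d spots in %d clusters (modularity %.3f)\n",
              length(x$labels), x$n_clusters, x$modularity))
  invisible(x)
}

.contingency <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2) stop("labelings must have length >= 2")
  unclass(table(a, b))
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two labelings; 1 for
#' identical partitions, about 0 for independent ones. Invariant to label
#' permutation and symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Numeric scalar in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  ct <- .contingency(labels_a, labels_b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

.entropy <- function(sizes) {
  p <- sizes[sizes > 0] / sum(sizes)
  -sum(p * log(p))
}

.mutual_information <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  sum(nij / n * log(n * nij / (a[nz[, 1]] * b[nz[, 2]])))
}

#' Normalized mutual information
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies. By the entropy-0 convention a single-cluster labeling gives
#' NMI = 0 against anything.
#'
#' @inheritParams ari
#' @return Numeric scalar in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b) {
  ct <- .contingency(labels_a, labels_b)
  h_a <- .entropy(rowSums(ct)); h_b <- .entropy(colSums(ct))
  if (h_a == 0 || h_b == 0) return(0)
  .mutual_information(ct) / ((h_a + h_b) / 2)
}

# expected mutual information under the permutation (hypergeometric) model
.expected_mi <- function(a, b, n) {
  emi <- 0
  lf <- lfactorial
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / n * log(n * nij / (a[i] * b[j]))
      lp <- lf(a[i]) + lf(b[j]) + lf(n - a[i]) + lf(n - b[j]) -
        lf(n) - lf(nij) - lf(a[i] - nij) - lf(b[j] - nij) -
        lf(n - a[i] - b[j] + nij)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance under the permutation model
#' and normalized by the arithmetic mean of the entropies:
#' `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])`. Near 0 for independent
#' labelings regardless of cluster counts; 1 for identical non-degenerate
#' partitions.
#'
#' @inheritParams ari
#' @return Numeric scalar (at most 1).
#' @export
ami <- function(labels_a, labels_b) {
  ct <- .contingency(labels_a, labels_b)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  h_a <- .entropy(a); h_b <- .entropy(b)
  if (h_a == 0 || h_b == 0) return(0)
  mi <- .mutual_information(ct)
  emi <- .expected_mi(a, b, n)
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

#' Write a cluster assignment to TSV
#'
#' @param clusters A `cluster_assignment` object.
#' @param path Output TSV path (columns `spot_id`, `cluster`).
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(spot_id = names(clusters$labels),
                   cluster = unname(clusters$labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
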