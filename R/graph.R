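#' K-nearest-neighbour expression similarity graph
#'
#' Builds an undirected graph over spots in which an edge joins i and j iff
#' j is among the k nearest neighbours of i in Euclidean distance over the
#' normalized expression matrix, or vice versa (union symmetrisation).
#' Every edge carries weight `W1`.
#'
#' @param X Spots x genes numeric matrix (typically `norm$X`).
#' @param k Number of nearest neighbours (1 <= k < number of spots).
#' @param W1 Edge weight for similarity edges (default 1).
#' @return Symmetric sparse `dgCMatrix` adjacency with entries `W1`.
#' @export
knn_expression_graph <- function(X, k, W1 = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of spots")
  d2 <- .squared_distances(X)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  i <- rep(seq_len(n), k)
  j <- as.vector(nn)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A <- ((A + Matrix::t(A)) > 0) * W1   # union symmetrisation
  dimnames(A) <- list(rownames(X), rownames(X))
  methods::as(A, "CsparseMatrix")
}

.squared_distances <- function(X) {
  r <- rowSums(X^2)
  d2 <- outer(r, r, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' Add a spatial-adjacency bonus to graph edges
#'
#' For every existing edge whose endpoints lie within `radius` of each
#' other in physical (array) coordinates, `W2` is added to the edge
#' weight. By default no new edges are created: physical adjacency only
#' reinforces expression-similarity edges. Setting `create_edges = TRUE`
#' additionally turns every spatially adjacent non-edge pair into an edge
#' of weight `W2`.
#'
#' @param A Symmetric adjacency matrix (sparse or dense) from
#'   [knn_expression_graph()].
#' @param coords Spot coordinate matrix (rows aligned with `A`).
#' @param radius Physical adjacency radius; `NULL` defaults to 1.5 times
#'   the minimum pairwise spot spacing, which covers 4-neighbourhoods on
#'   square grids and hexagonal Visium packing.
#' @param W2 Bonus weight (default 1).
#' @param create_edges Also create pure-spatial edges (default `FALSE`).
#' @return Updated sparse adjacency matrix.
#' @export
spatial_adjacency_bonus <- function(A, coords, radius = NULL, W2 = 1,
                                    create_edges = FALSE) {
  coords <- as.matrix(coords)
  if (is.null(radius)) radius <- default_adjacency_radius(coords)
  if (radius <= 0) stop("radius must be positive")
  d2 <- .squared_distances(coords)
  diag(d2) <- Inf
  near <- d2 <= radius^2
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  if (create_edges) {
    A <- A + W2 * Matrix::Matrix(near, sparse = TRUE)
  } else {
    tr <- Matrix::mat2triplet(methods::as(A, "TsparseMatrix"))
    add <- near[cbind(tr$i, tr$j)]
    A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x + W2 * add,
                              dims = dim(A), dimnames = dimnames(A))
  }
  methods::as(Matrix::drop0(A), "CsparseMatrix")
}

#' Default physical adjacency radius
#'
#' 1.5 times the minimum pairwise distance between spots.
#' @param coords Spot coordinate matrix.
#' @export
default_adjacency_radius <- function(coords) {
  d <- dist(as.matrix(coords))
  m <- min(d[d > 0])
  1.5 * m
}

#' Symmetric normalization of an adjacency matrix
#'
#' Computes `D^{-1/2} (A + sI) D^{-1/2}` where `s` is 1 when self loops
#' are requested (standard graph-convolution practice, prevents zero
#' rows) and `D` holds the row sums of the augmented matrix. Zero-degree
#' rows map to zero rows.
#'
#' @param A Symmetric non-negative adjacency matrix.
#' @param self_loops Add unit self loops before normalising (default
#'   `TRUE`).
#' @return Dense symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(A, self_loops = TRUE) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("adjacency matrix must be symmetric")
  if (self_loops) diag(A) <- diag(A) + 1
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  An <- A * outer(inv_sqrt, inv_sqrt)
  dimnames(An) <- dimnames(A)
  An
}

#' Build the fused spot graph
#'
#' Convenience wrapper chaining [knn_expression_graph()],
#' [spatial_adjacency_bonus()] and [normalize_adjacency()]: expression
#' similarity contributes `W1` per KNN edge, physical adjacency adds `W2`,
#' so off-diagonal weights lie in {0, W1, W2, W1+W2}.
#'
#' @param X Spots x genes matrix.
#' @param coords Spot coordinates (rows aligned with `X`).
#' @param k,W1,W2,radius,create_edges,self_loops See the stage functions.
#' @return An object of class `spot_graph`: list with `A` (sparse weighted
#'   adjacency), `A_norm` (dense symmetric normalization), `degree`, and
#'   `params`.
#' @export
build_spot_graph <- function(X, coords, k = 15, W1 = 1, W2 = 1,
                             radius = NULL, create_edges = FALSE,
                             self_loops = TRUE) {
  coords <- as.matrix(coords)
  if (is.null(radius)) radius <- default_adjacency_radius(coords)
  A <- knn_expression_graph(X, k = k, W1 = W1)
  A <- spatial_adjacency_bonus(A, coords, radius = radius, W2 = W2,
                               create_edges = create_edges)
  An <- normalize_adjacency(A, self_loops = self_loops)
  structure(
    list(A = A, A_norm = An, degree = Matrix::rowSums(A),
         params = list(k = k, W1 = W1, W2 = W2, radius = radius,
                       create_edges = create_edges,
                       self_loops = self_loops)),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("spot_graph: %d spots, %d edges (k=%d, W1=%g, W2=%g, radius=%.3g)\n",
              nrow(x$A), Matrix::nnzero(x$A) / 2, x$params$k, x$params$W1,
              x$params$W2, x$params$radius))
  invisible(x)
}

#' Export a spot graph as an edge list
#'
#' Writes an `i, j, weight` TSV with one row per undirected edge (i < j).
#' @param graph A `spot_graph` object or adjacency matrix.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  A <- if (is(graph, "spot_graph")) graph$A else graph
  tr <- Matrix::mat2triplet(methods::as(A, "TsparseMatrix"))
  keep <- tr$i < tr$j
  df <- data.frame(i = tr$i[keep], j = tr$j[keep], weight = tr$x[keep])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
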