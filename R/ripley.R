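# Multi-distance spatial pattern analysis of CNA events.
#
# K(d) = (1/lambda) * sum_i sum_{j != i} 1[d_ij <= d] / N over the N event
# spots, without edge correction; lambda = N / (number of spots in the
# tissue), treating the spot lattice itself as the sampled domain with unit
# cell area. The null distribution comes from resampling N spots uniformly
# without replacement from the lattice, which is computed on the identical
# domain and therefore absorbs boundary bias by construction.

.pair_counts <- function(dvec, d_grid) {
  vapply(d_grid, function(d) 2 * sum(dvec <= d), numeric(1))
}

#' Ripley's K-function over a spot lattice
#'
#' Empirical K-function of a set of event points, with the event density
#' taken relative to the full spot lattice (`lambda = N /
#' nrow(domain_points)`, unit cell area) and no edge correction.
#'
#' @param points Coordinates of the event spots (matrix-like, two
#'   columns).
#' @param d_grid Increasing vector of distances.
#' @param domain_points Coordinates of all spots in the tissue (defines
#'   the domain size); defaults to `points` itself.
#' @return Numeric vector `K(d)`, non-negative and non-decreasing, with
#'   attribute `lambda`. Fewer than 2 points gives all-`NA` values with
#'   attribute `undefined = TRUE`.
#' @export
ripley_k <- function(points, d_grid, domain_points = points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) {
    k <- rep(NA_real_, length(d_grid))
    attr(k, "undefined") <- TRUE
    return(k)
  }
  lambda <- n / nrow(as.matrix(domain_points))
  dvec <- as.vector(dist(points))
  k <- .pair_counts(dvec, d_grid) / (lambda * n)
  attr(k, "lambda") <- lambda
  k
}

#' Monte-Carlo CSR envelope and spatial-pattern labels
#'
#' Compares the observed K-function of an event spot set against `R`
#' resamples of the same number of spots drawn uniformly without
#' replacement from the lattice (the complete-spatial-randomness null).
#' Per distance, the Monte-Carlo p-value for the hypothesis
#' `K_obs <= K_exp` is `(1 + #\{K_sim >= K_obs\}) / (R + 1)` and its
#' rejection labels the pattern *aggregation*; the p-value for
#' `K_obs >= K_exp` uses `<=` and its rejection labels the pattern
#' *dispersed*; otherwise the label is *CSR*. Labels are mutually
#' exclusive per distance; no multiplicity correction is applied across
#' distances.
#'
#' @param event_spots Indices (integer/logical, or spot names matching
#'   `rownames(all_spots)`) of the spots carrying the event.
#' @param all_spots Coordinates of every spot in the tissue.
#' @param d_grid Distances at which to evaluate K; `NULL` picks 10
#'   distances from the minimum spot spacing to a quarter of the domain
#'   diameter.
#' @param R Number of resamples (default 999; at least 99).
#' @param seed RNG seed for the resampling.
#' @param alpha Per-distance significance level (default 0.05).
#' @return Object of class `kfunction_result`: data frame with columns
#'   `d`, `K_obs`, `K_exp_mean`, `lo`, `hi` (alpha/2 and 1 - alpha/2
#'   envelope quantiles), `p_agg`, `p_disp`, `label`; attributes `R`,
#'   `seed`, `n_events`.
#' @export
csr_envelope <- function(event_spots, all_spots, d_grid = NULL, R = 999,
                         seed = 0, alpha = 0.05) {
  all_spots <- as.matrix(all_spots)
  n <- nrow(all_spots)
  if (is.logical(event_spots)) event_spots <- which(event_spots)
  if (is.character(event_spots))
    event_spots <- match(event_spots, rownames(all_spots))
  event_spots <- as.integer(event_spots)
  if (anyNA(event_spots) || any(event_spots < 1) || any(event_spots > n))
    stop("event_spots must index rows of all_spots")
  N <- length(event_spots)
  if (N > n) stop("more event spots than spots in the domain")
  if (N < 2) stop("need at least 2 event spots")
  if (R < 99) stop("R must be at least 99")
  D <- as.matrix(dist(all_spots))
  if (is.null(d_grid)) {
    dmin <- min(D[D > 0])
    d_grid <- seq(dmin, max(D) / 4, length.out = 10)
  }
  lambda <- N / n
  ut <- upper.tri(matrix(0, N, N))
  k_of <- function(idx) {
    .pair_counts(D[idx, idx][ut], d_grid) / (lambda * N)
  }
  K_obs <- k_of(event_spots)
  set.seed(seed)
  K_sim <- matrix(NA_real_, R, length(d_grid))
  for (r in seq_len(R)) K_sim[r, ] <- k_of(sample.int(n, N))
  p_agg <- (1 + colSums(K_sim >= rep(K_obs, each = R))) / (R + 1)
  p_disp <- (1 + colSums(K_sim <= rep(K_obs, each = R))) / (R + 1)
  label <- ifelse(p_agg <= alpha, "aggregation",
                  ifelse(p_disp <= alpha, "dispersed", "CSR"))
  out <- data.frame(
    d = d_grid, K_obs = K_obs, K_exp_mean = colMeans(K_sim),
    lo = apply(K_sim, 2, quantile, alpha / 2),
    hi = apply(K_sim, 2, quantile, 1 - alpha / 2),
    p_agg = p_agg, p_disp = p_disp, label = label
  )
  rownames(out) <- NULL
  structure(out, class = c("kfunction_result", "data.frame"),
            R = R, seed = seed, n_events = N, alpha = alpha)
}
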