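#' Median filter with shrinking edge windows
#'
#' `out[i]` is the median of the window of half-width `(window - 1)/2`
#' centred on `i`, truncated at the sequence ends (no padding: edge
#' windows shrink, and even-sized edge windows use the mean-of-middles
#' median). `window = 1` is the identity.
#'
#' @param s Numeric vector.
#' @param window Odd integer window size >= 1.
#' @return Numeric vector of the same length.
#' @export
median_filter <- function(s, window) {
  if (length(window) != 1 || window < 1 || window %% 2 == 0)
    stop("window must be a single odd integer >= 1")
  cpp_median_filter(as.numeric(s), as.integer(window))
}

#' Multi-level median filtering
#'
#' Reduces the dependence on a single window size by combining median
#' filters at several scales, then applying one final median filter. The
#' default `combine = "cascade"` applies the windows in sequence; the
#' alternative `"across_scale"` filters the original sequence once per
#' window and takes the per-position median across the scale outputs.
#' Windows are clipped per sequence to the largest odd value not
#' exceeding the sequence length, so short chromosome arms stay
#' well-defined. Idempotent on constant input.
#'
#' @param s Numeric vector.
#' @param windows Ordered odd integer window sizes (default `c(11, 31,
#'   51)`).
#' @param final_window Odd window of the final pass (default 5).
#' @param combine `"cascade"` (default) or `"across_scale"`.
#' @return Numeric vector of the same length.
#' @export
multilevel_filter <- function(s, windows = c(11, 31, 51), final_window = 5,
                              combine = c("cascade", "across_scale")) {
  combine <- match.arg(combine)
  if (any(windows < 1) || any(windows %% 2 == 0))
    stop("all windows must be odd integers >= 1")
  if (final_window < 1 || final_window %% 2 == 0)
    stop("final_window must be a single odd integer >= 1")
  cpp_multilevel_filter(as.numeric(s), as.integer(windows),
                        as.integer(final_window),
                        combine == "across_scale")
}

#' Construct/validate HMM parameters
#'
#' Three CNA states in fixed order (deletion, neutral, amplification)
#' with Gaussian emissions. `transition` rows must sum to 1 (tolerance
#' 1e-9), `initial` must sum to 1, emission standard deviations must be
#' positive, and the means must be non-decreasing across the state order.
#'
#' @param transition 3x3 row-stochastic transition matrix.
#' @param initial Length-3 initial state distribution.
#' @param mu Length-3 emission means (deletion <= neutral <=
#'   amplification).
#' @param sigma Length-3 positive emission standard deviations.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(transition, initial, mu, sigma) {
  transition <- matrix(as.numeric(transition), 3, 3)
  stopifnot(length(initial) == 3, length(mu) == 3, length(sigma) == 3)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (is.unsorted(mu)) stop("emission means must satisfy mu_del <= mu_neu <= mu_amp")
  structure(list(transition = transition, initial = as.numeric(initial),
                 mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params (deletion, neutral, amplification)\n")
  cat("  mu    =", signif(x$mu, 4), "\n")
  cat("  sigma =", signif(x$sigma, 4), "\n")
  cat("  diag(T) =", signif(diag(x$transition), 4), "\n")
  invisible(x)
}

#' Deterministic data-adaptive HMM initialisation
#'
#' Emission means at the 10th/50th/90th percentiles of the pooled values,
#' a common emission standard deviation equal to the pooled standard
#' deviation (floored), 0.9 self-transitions and a uniform initial
#' distribution.
#'
#' @param values Pooled (smoothed) expression values.
#' @param sigma_floor Lower bound for the emission standard deviation.
#' @return An [hmm_params] object.
#' @export
hmm_init <- function(values, sigma_floor = 1e-3) {
  values <- values[is.finite(values)]
  mu <- unname(quantile(values, c(0.1, 0.5, 0.9)))
  s <- max(sd(values), sigma_floor, na.rm = TRUE)
  if (!is.finite(s)) s <- sigma_floor
  tm <- matrix(0.05, 3, 3); diag(tm) <- 0.9
  hmm_params(tm, rep(1 / 3, 3), mu, rep(s, 3))
}

#' Baum-Welch estimation of the 3-state CNA HMM
#'
#' Expectation-maximisation over a pool of observation sequences with a
#' scaled forward-backward E-step. The per-iteration total log-likelihood
#' is non-decreasing; iteration stops when its relative change drops
#' below `tol` or after `max_iter` iterations. After convergence the
#' states are sorted by emission mean (with the consistent permutation of
#' the transition matrix and initial distribution) so that the state
#' order deletion <= neutral <= amplification always holds.
#'
#' @param sequences List of numeric vectors, each of length >= 2.
#' @param init Optional [hmm_params] starting point; default
#'   [hmm_init()] on the pooled values.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood change for convergence (default
#'   1e-8).
#' @param sigma_floor Emission standard deviations are clamped below at
#'   this floor (default 1e-3), with a message when the clamp fires.
#' @return An [hmm_params] object with extra elements `loglik_trace`,
#'   `n_iter` and `converged`.
#' @export
baum_welch <- function(sequences, init = NULL, max_iter = 100, tol = 1e-8,
                       sigma_floor = 1e-3) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.numeric)
  if (any(vapply(sequences, length, 1L) < 2))
    stop("all sequences must have length >= 2")
  if (is.null(init)) init <- hmm_init(unlist(sequences), sigma_floor)
  stopifnot(is(init, "hmm_params"))
  tm <- init$transition; pi0 <- init$initial
  mu <- init$mu; sigma <- pmax(init$sigma, sigma_floor)
  trace <- numeric(0)
  clamped <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- cpp_em_step(sequences, pi0, tm, mu, sigma)
    trace <- c(trace, es$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it]) + 1)) {
      converged <- TRUE
      break
    }
    # M-step
    if (sum(es$start) > 0) pi0 <- es$start / sum(es$start)
    rs <- rowSums(es$trans)
    for (i in 1:3) if (rs[i] > 0) tm[i, ] <- es$trans[i, ] / rs[i]
    for (j in 1:3) {
      if (es$w[j] > 0) {
        mu[j] <- es$wx[j] / es$w[j]
        v <- es$wx2[j] / es$w[j] - mu[j]^2
        sigma[j] <- sqrt(max(v, 0))
      }
    }
    if (any(sigma < sigma_floor)) {
      clamped <- TRUE
      sigma <- pmax(sigma, sigma_floor)
    }
  }
  if (clamped)
    message(sprintf("emission sd clamped at floor %g", sigma_floor))
  perm <- order(mu)
  out <- hmm_params(tm[perm, perm], pi0[perm], mu[perm], sigma[perm])
  out$loglik_trace <- trace
  out$n_iter <- length(trace)
  out$converged <- converged
  out
}

#' Viterbi decoding of a CNA state path
#'
#' Exact maximum-probability state path under the 3-state Gaussian HMM,
#' computed by dynamic programming in log space. Ties are broken toward
#' the lower state index (deletion < neutral < amplification).
#'
#' @param s Numeric observation sequence (smoothed expression).
#' @param params An [hmm_params] object.
#' @return List with `states` (integer vector over -1 = deletion, 0 =
#'   neutral, 1 = amplification) and `log_prob` of the decoded path.
#' @export
viterbi <- function(s, params) {
  stopifnot(is(params, "hmm_params"))
  res <- cpp_viterbi(as.numeric(s), params$initial, params$transition,
                     params$mu, params$sigma)
  list(states = res$path - 2L, log_prob = res$log_prob)
}

.as_cluster_labels <- function(clusters, spot_ids) {
  labels <- if (is(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (!is.null(names(labels))) {
    if (!all(spot_ids %in% names(labels)))
      stop("clusters must cover all spots")
    labels <- labels[spot_ids]
  } else if (length(labels) != length(spot_ids)) {
    stop("clusters must cover all spots")
  }
  setNames(as.vector(labels), spot_ids)
}

#' Infer the per-spot CNA profile
#'
#' The full CNA-calling stage: chromosome-arm sequences of the normalized
#' matrix are smoothed by multi-level median filtering; for each cluster
#' one 3-state Gaussian HMM is fitted by [baum_welch()] on the pooled
#' smoothed arm sequences of its member spots; every spot's every arm is
#' then decoded individually with [viterbi()] (no cross-arm
#' transitions). Clusters with fewer than `min_obs` pooled observations
#' fall back to a single global fit. A fitted deletion or amplification
#' state whose mean lies within `min_delta` of the neutral mean is
#' collapsed into neutral at decoding time, which keeps CNA-free data
#' from being split across spurious states.
#'
#' @param norm A `normalized_expression` object (or spots x genes
#'   matrix).
#' @param ann A [gene_annotation][load_gene_annotation] object.
#' @param clusters A [cluster_assignment][louvain_cluster] or a vector of
#'   cluster labels covering all spots.
#' @param windows,final_window,combine Multi-level filter settings, see
#'   [multilevel_filter()].
#' @param fit_level `"cluster"` (default: one HMM per cluster) or
#'   `"global"` (a single HMM pooled over all spots).
#' @param min_obs Minimum pooled observations for a per-cluster fit
#'   (default 500).
#' @param min_delta Minimum distance of the deletion/amplification
#'   emission mean from the neutral mean, in centred log-expression
#'   units, for the state to be callable (default 0.2, about half the
#'   expression shift a single-copy change produces at moderate
#'   expression).
#' @param normal_clusters Optional cluster labels to set all-neutral
#'   without fitting (designated reference clusters).
#' @param max_iter,tol,sigma_floor Passed to [baum_welch()].
#' @return Object of class `cna_profile`: list with `states` (spots x
#'   annotated-genes integer matrix over -1/0/1), `log_lik` (spots x
#'   arms decode log-probabilities), `params` (per-cluster
#'   [hmm_params]), `clusters`, and `arms`.
#' @export
infer_cna <- function(norm, ann, clusters, windows = c(11, 31, 51),
                      final_window = 5,
                      combine = c("cascade", "across_scale"),
                      fit_level = c("cluster", "global"), min_obs = 500,
                      min_delta = 0.2, normal_clusters = NULL,
                      max_iter = 100, tol = 1e-8, sigma_floor = 1e-3) {
  combine <- match.arg(combine)
  fit_level <- match.arg(fit_level)
  X <- if (is(norm, "normalized_expression")) norm$X else as.matrix(norm)
  stopifnot(is(ann, "gene_annotation"))
  X <- X[, colnames(X) %in% ann$gene_id, drop = FALSE]
  if (ncol(X) == 0) stop("no annotated genes in the matrix")
  arms <- build_arm_sequences(X, ann)
  labels <- .as_cluster_labels(clusters, rownames(X))

  arm_cols <- lapply(arms$arms, `[[`, "cols")
  Xs <- cpp_smooth_matrix(X, arm_cols, as.integer(windows),
                          as.integer(final_window),
                          combine == "across_scale")
  dimnames(Xs) <- dimnames(X)

  n_spot <- nrow(X)
  spot_seqs <- function(spots) {
    out <- vector("list", length(spots) * length(arm_cols))
    k <- 1
    for (i in spots) {
      for (a in arm_cols) {
        out[[k]] <- Xs[i, a]
        k <- k + 1
      }
    }
    out[vapply(out, length, 1L) >= 2]
  }

  global_fit <- NULL
  get_global <- function() {
    if (is.null(global_fit))
      global_fit <<- baum_welch(spot_seqs(seq_len(n_spot)),
                                max_iter = max_iter, tol = tol,
                                sigma_floor = sigma_floor)
    global_fit
  }

  uniq <- sort(unique(labels))
  params <- list()
  for (cl in uniq) {
    if (!is.null(normal_clusters) && cl %in% normal_clusters) {
      params[[as.character(cl)]] <- "neutral"
      next
    }
    if (fit_level == "global") {
      params[[as.character(cl)]] <- get_global()
      next
    }
    spots <- which(labels == cl)
    seqs <- spot_seqs(spots)
    n_obs <- sum(vapply(seqs, length, 1L))
    if (n_obs < min_obs) {
      message(sprintf("cluster %s has %d observations (< %d); using the global fit",
                      cl, n_obs, min_obs))
      params[[as.character(cl)]] <- get_global()
    } else {
      params[[as.character(cl)]] <- baum_welch(seqs, max_iter = max_iter,
                                               tol = tol,
                                               sigma_floor = sigma_floor)
    }
  }

  states <- matrix(0L, n_spot, ncol(X), dimnames = dimnames(X))
  log_lik <- matrix(NA_real_, n_spot, length(arm_cols),
                    dimnames = list(rownames(X), names(arm_cols)))
  for (cl in uniq) {
    spots <- which(labels == cl)
    fit <- params[[as.character(cl)]]
    if (identical(fit, "neutral")) {
      log_lik[spots, ] <- 0
      next
    }
    # collapse near-neutral states: deletions/amplifications whose fitted
    # mean is within min_delta of the neutral mean are not callable
    callable <- c(fit$mu[2] - fit$mu[1] >= min_delta, TRUE,
                  fit$mu[3] - fit$mu[2] >= min_delta)
    for (i in spots) {
      for (a in seq_along(arm_cols)) {
        v <- cpp_viterbi(Xs[i, arm_cols[[a]]], fit$initial, fit$transition,
                         fit$mu, fit$sigma)
        st <- v$path - 2L
        st[!callable[v$path]] <- 0L
        states[i, arm_cols[[a]]] <- st
        log_lik[i, a] <- v$log_prob
      }
    }
  }
  structure(
    list(states = states, log_lik = log_lik, params = params,
         clusters = labels, arms = arms,
         settings = list(windows = windows, final_window = final_window,
                         combine = combine, fit_level = fit_level,
                         min_obs = min_obs, min_delta = min_delta)),
    class = "cna_profile"
  )
}

#' @export
print.cna_profile <- function(x, ...) {
  tab <- table(factor(x$states, levels = c(-1, 0, 1),
                      labels = c("deletion", "neutral", "amplification")))
  cat(sprintf("cna_profile: %d spots x %d genes\n", nrow(x$states),
              ncol(x$states)))
  print(round(tab / sum(tab), 4))
  invisible(x)
}

#' CNA call accuracy against a ground truth
#'
#' True- and false-positive rates of deletion and amplification calls
#' over the (spot, gene) grid. For an event state `s`, TPR is the
#' fraction of truly-`s` entries called `s`, and FPR the fraction of
#' not-`s` entries called `s`.
#'
#' @param called Integer matrix over -1/0/1 (e.g. `profile$states`).
#' @param truth Matching ground-truth matrix over -1/0/1.
#' @return Data frame with columns `state`, `tpr`, `fpr`, `n_true`.
#' @export
cna_accuracy <- function(called, truth) {
  if (is(called, "cna_profile")) called <- called$states
  truth <- truth[rownames(called), colnames(called), drop = FALSE]
  stopifnot(all(dim(called) == dim(truth)))
  one <- function(s) {
    pos <- truth == s
    data.frame(state = if (s == -1) "deletion" else "amplification",
               tpr = sum(called == s & pos) / sum(pos),
               fpr = sum(called == s & !pos) / sum(!pos),
               n_true = sum(pos))
  }
  rbind(one(-1L), one(1L))
}

#' Write a CNA profile to disk
#'
#' Writes the spot x gene state matrix as TSV (-1/0/1), a long-format
#' table (spot, gene, chrom, arm, state), and the per-cluster HMM
#' parameters as JSON.
#'
#' @param profile A `cna_profile`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cna_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat_path <- file.path(dir, "cna_states.tsv")
  df <- data.frame(spot_id = rownames(profile$states), profile$states,
                   check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)

  long <- do.call(rbind, lapply(profile$arms$arms, function(a)
    data.frame(gene = a$gene_ids, chrom = a$chrom, arm = a$arm,
               col = a$cols)))
  long_path <- file.path(dir, "cna_long.tsv")
  ll <- data.frame(
    spot = rep(rownames(profile$states), times = nrow(long)),
    gene = rep(long$gene, each = nrow(profile$states)),
    chrom = rep(long$chrom, each = nrow(profile$states)),
    arm = rep(long$arm, each = nrow(profile$states)),
    state = as.vector(profile$states[, long$col])
  )
  write.table(ll, long_path, sep = "\t", quote = FALSE, row.names = FALSE)

  par_path <- file.path(dir, "hmm_params.json")
  ser <- lapply(profile$params, function(p) {
    if (identical(p, "neutral")) return(list(designated = "neutral"))
    list(transition = p$transition, initial = p$initial, mu = p$mu,
         sigma = p$sigma, n_iter = p$n_iter, converged = p$converged)
  })
  jsonlite::write_json(ser, par_path, auto_unbox = TRUE, digits = NA)
  invisible(c(mat_path, long_path, par_path))
}
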