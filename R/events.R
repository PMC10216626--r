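# Co-occurrence / mutual-exclusion analysis of CNA events within clusters,
# and per-cluster differential CNA against a designated normal cluster.

#' Binary CNA event tables per cluster
#'
#' For every cluster and every (gene, state) pair with state deletion or
#' amplification, builds the binary spot vector of the event. Events are
#' kept when their spot count reaches `ceiling(min_freq * n)` (compared
#' with `>=`), which excludes degenerate near-empty tables.
#'
#' @param profile A [cna_profile][infer_cna] (or a -1/0/1 state matrix).
#' @param clusters Cluster labels covering the profile spots; defaults to
#'   the labels stored in the profile.
#' @param min_freq Minimum event frequency as a fraction of the cluster's
#'   spots (default 0.05).
#' @return Named list (one element per cluster) of lists with `events`
#'   (logical spots x events matrix, event names like `"GENE1-amp"`,
#'   `"GENE2-del"`) and `spot_ids`.
#' @export
cna_event_table <- function(profile, clusters = NULL, min_freq = 0.05) {
  states <- if (is(profile, "cna_profile")) profile$states else profile
  if (is.null(clusters)) {
    stopifnot(is(profile, "cna_profile"))
    clusters <- profile$clusters
  }
  labels <- .as_cluster_labels(clusters, rownames(states))
  out <- list()
  for (cl in sort(unique(labels))) {
    spots <- which(labels == cl)
    n_c <- length(spots)
    thresh <- ceiling(min_freq * n_c)
    mats <- list()
    for (s in c(-1L, 1L)) {
      ev <- states[spots, , drop = FALSE] == s
      keep <- colSums(ev) >= thresh
      if (any(keep)) {
        m <- ev[, keep, drop = FALSE]
        colnames(m) <- paste0(colnames(m), if (s == 1L) "-amp" else "-del")
        mats[[length(mats) + 1]] <- m
      }
    }
    events <- if (length(mats)) do.call(cbind, mats)
              else matrix(FALSE, n_c, 0, dimnames = list(rownames(states)[spots], NULL))
    out[[as.character(cl)]] <- list(events = events,
                                    spot_ids = rownames(states)[spots])
  }
  structure(out, class = "cna_event_table", min_freq = min_freq)
}

#' Test one event pair for co-occurrence / mutual exclusion
#'
#' One-sided Fisher's exact tests on the 2x2 contingency table of two
#' binary event vectors over the same spots: enrichment (odds ratio > 1,
#' co-occurrence) and depletion (mutual exclusion). The direction is the
#' side with the smaller p-value. Degenerate margins (an all-zero or
#' all-one vector) are flagged untestable.
#'
#' @param event_a,event_b Logical (or 0/1) vectors of equal length.
#' @return One-row data frame with the table counts (`n11` both, `n10`,
#'   `n01`, `n00` neither), `odds_ratio` (sample OR), `p_cooccur`,
#'   `p_mutex`, `p` (the smaller side) and `direction`.
#' @export
cooccurrence_test <- function(event_a, event_b) {
  a <- as.logical(event_a); b <- as.logical(event_b)
  if (length(a) != length(b)) stop("event vectors must have equal length")
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
  n00 <- sum(!a & !b)
  res <- data.frame(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                    odds_ratio = NA_real_, p_cooccur = NA_real_,
                    p_mutex = NA_real_, p = NA_real_,
                    direction = "untestable", stringsAsFactors = FALSE)
  if (all(a) || !any(a) || all(b) || !any(b)) return(res)
  tab <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE)
  res$odds_ratio <- (n11 * n00) / (n10 * n01)
  res$p_cooccur <- fisher.test(tab, alternative = "greater")$p.value
  res$p_mutex <- fisher.test(tab, alternative = "less")$p.value
  res$p <- min(res$p_cooccur, res$p_mutex)
  res$direction <- if (res$p_cooccur < res$p_mutex) "co-occurrence"
                   else if (res$p_mutex < res$p_cooccur) "mutual-exclusion"
                   else "none"
  res
}

#' Pairwise co-occurrence analysis within clusters
#'
#' Runs [cooccurrence_test()] on every pair of events of every cluster in
#' an event table and applies Benjamini-Hochberg correction to the
#' selected-side p-values across all testable pairs within each cluster.
#'
#' @param event_table A [cna_event_table()] result.
#' @param max_events Optional cap: per cluster only the `max_events` most
#'   frequent events are paired (keeps large gene panels tractable);
#'   `Inf` tests all pairs.
#' @return Data frame with one row per tested pair: `cluster`, `event_a`,
#'   `event_b`, the [cooccurrence_test()] columns, and `q` (BH within
#'   cluster).
#' @export
cooccurrence_analysis <- function(event_table, max_events = Inf) {
  rows <- list()
  for (cl in names(event_table)) {
    ev <- event_table[[cl]]$events
    if (ncol(ev) < 2) next
    if (is.finite(max_events) && ncol(ev) > max_events) {
      ord <- order(colSums(ev), decreasing = TRUE)
      ev <- ev[, sort(ord[seq_len(max_events)]), drop = FALSE]
    }
    pairs <- utils::combn(ncol(ev), 2)
    res <- lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      cbind(data.frame(cluster = cl, event_a = colnames(ev)[i],
                       event_b = colnames(ev)[j],
                       stringsAsFactors = FALSE),
            cooccurrence_test(ev[, i], ev[, j]))
    })
    res <- do.call(rbind, res)
    res$q <- NA_real_
    testable <- res$direction != "untestable"
    res$q[testable] <- p.adjust(res$p[testable], method = "BH")
    rows[[cl]] <- res
  }
  if (length(rows) == 0) {
    return(data.frame(cluster = character(), event_a = character(),
                      event_b = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential CNA between clusters and a normal cluster
#'
#' For every gene, every non-normal cluster and each event type
#' (deletion, amplification), tests whether the event is enriched in the
#' cluster relative to the designated normal cluster (one-sided Fisher's
#' exact test on the 2x2 table event/no-event x cluster/normal, computed
#' as the hypergeometric upper tail). p-values are BH-adjusted across
#' genes within each (cluster, event type), and the score is
#' `-log10(q)` signed positive for amplification and negative for
#' deletion.
#'
#' @param profile A [cna_profile][infer_cna] (or state matrix).
#' @param clusters Cluster labels; defaults to the profile's.
#' @param normal_cluster Label of the designated normal/reference
#'   cluster.
#' @return Data frame: `gene`, `cluster`, `state`, `n_event_cluster`,
#'   `n_event_normal`, `n_cluster`, `n_normal`, `p`, `q`, `score`.
#' @export
differential_cna <- function(profile, clusters = NULL, normal_cluster) {
  states <- if (is(profile, "cna_profile")) profile$states else profile
  if (is.null(clusters)) {
    stopifnot(is(profile, "cna_profile"))
    clusters <- profile$clusters
  }
  labels <- .as_cluster_labels(clusters, rownames(states))
  if (!normal_cluster %in% labels) stop("normal_cluster not found in labels")
  normal <- which(labels == normal_cluster)
  n_norm <- length(normal)
  rows <- list()
  for (cl in setdiff(sort(unique(labels)), normal_cluster)) {
    spots <- which(labels == cl)
    n_c <- length(spots)
    for (s in c(-1L, 1L)) {
      x <- colSums(states[spots, , drop = FALSE] == s)
      x0 <- colSums(states[normal, , drop = FALSE] == s)
      # one-sided Fisher (enrichment): hypergeometric upper tail
      p <- stats::phyper(x - 1, x + x0, n_c + n_norm - x - x0, n_c,
                         lower.tail = FALSE)
      q <- p.adjust(p, method = "BH")
      rows[[length(rows) + 1]] <- data.frame(
        gene = colnames(states), cluster = cl,
        state = if (s == 1L) "amplification" else "deletion",
        n_event_cluster = x, n_event_normal = x0,
        n_cluster = n_c, n_normal = n_norm, p = p, q = q,
        score = (if (s == 1L) 1 else -1) * -log10(pmax(q, 1e-300)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
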