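# Fully synthetic spatial transcriptomes with known clone structure and CNA
# ground truth. The generator emulates the situation the pipeline targets:
# a spatial lattice of spots partitioned into spatially contiguous clones
# (tumour clones aggregate locally), each clone carrying arm-level CNA
# segments that scale expression multiplicatively, with overdispersed count
# noise, per-spot library-size variation and dropout.

#' Spot coordinates of a rectangular lattice
#'
#' @param nrow,ncol Grid dimensions.
#' @return Matrix with columns `x`, `y` (unit spacing), one row per spot,
#'   row names `s0001`, ...
#' @export
lattice_coords <- function(nrow, ncol) {
  g <- expand.grid(x = seq_len(ncol), y = seq_len(nrow))
  m <- as.matrix(g)
  rownames(m) <- sprintf("s%04d", seq_len(nrow(m)))
  m
}

.default_segments <- function(n_clones) {
  seg <- data.frame(
    clone = c(1, 1, 2, 2, 3, 3, 3),
    chrom = c("1", "2", "3", "1", "2", "4", "5"),
    arm   = c("p", "q", "p", "q", "p", "q", "p"),
    state = c(-1L, 1L, 1L, -1L, -1L, 1L, 1L),
    fold  = c(0.5, 1.5, 1.5, 0.5, 0.5, 1.5, 1.5),
    stringsAsFactors = FALSE
  )
  seg[seg$clone <= n_clones, , drop = FALSE]
}

#' Simulation configuration
#'
#' The default configuration is the package's reference study condition:
#' a 40 x 40 lattice partitioned by Voronoi regions (fixed, well-spread
#' seeds) into one normal region and three tumour clones; 2,000 genes on
#' 10 synthetic chromosome arms (5 chromosomes x p/q, 200 genes each);
#' arm-level CNA segments with deletion fold 0.5 and amplification fold
#' 1.5; log-normal per-gene baselines; negative-binomial counts
#' (dispersion 0.3) with log-normal library-size variation and 5%
#' dropout.
#'
#' @param grid Lattice dimensions `c(rows, cols)` (default `c(40, 40)`).
#' @param n_clones Number of tumour clones besides the normal region
#'   (default 3).
#' @param segments Data frame of CNA segments with columns `clone`,
#'   `chrom`, `arm`, `state` (-1/1), `fold`, and optionally `start_gene`,
#'   `end_gene` (1-based gene ranks within the arm; defaults cover the
#'   whole arm). Deletion folds must be < 1 < amplification folds.
#' @param n_chrom,genes_per_arm Synthetic genome size (defaults 5 and
#'   200).
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene
#'   baseline expression (defaults 1 and 1).
#' @param libsize_sdlog Log-normal sd of the per-spot library factor
#'   (default 0.15).
#' @param noise `"nb"` (negative binomial, default) or `"poisson"`.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`,
#'   default 0.3).
#' @param dropout Per-count thinning probability (default 0.05).
#' @param seed RNG seed (default 1).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(grid = c(40, 40), n_clones = 3,
                              segments = NULL, n_chrom = 5,
                              genes_per_arm = 200, baseline_meanlog = 1,
                              baseline_sdlog = 1, libsize_sdlog = 0.15,
                              noise = c("nb", "poisson"), dispersion = 0.3,
                              dropout = 0.05, seed = 1) {
  noise <- match.arg(noise)
  if (is.null(segments)) segments <- .default_segments(n_clones)
  if (is.null(segments$start_gene)) segments$start_gene <- 1L
  if (is.null(segments$end_gene)) segments$end_gene <- genes_per_arm
  stopifnot(all(segments$fold > 0),
            all(segments$fold[segments$state == -1L] < 1),
            all(segments$fold[segments$state == 1L] > 1),
            dropout >= 0, dropout < 1, dispersion > 0)
  # overlapping segments within a clone are a configuration error
  key <- paste(segments$clone, segments$chrom, segments$arm)
  for (k in unique(key)) {
    d <- segments[key == k, , drop = FALSE]
    if (nrow(d) > 1) {
      d <- d[order(d$start_gene), ]
      if (any(d$start_gene[-1] <= d$end_gene[-nrow(d)]))
        stop("overlapping CNA segments within a clone on ", k)
    }
  }
  structure(list(grid = grid, n_clones = n_clones, segments = segments,
                 n_chrom = n_chrom, genes_per_arm = genes_per_arm,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 libsize_sdlog = libsize_sdlog, noise = noise,
                 dispersion = dispersion, dropout = dropout, seed = seed),
            class = "simulation_config")
}

# deterministic well-spread Voronoi seeds: region 1 is normal
.voronoi_regions <- function(coords, k) {
  ctr <- c(mean(range(coords[, 1])), mean(range(coords[, 2])))
  r <- 0.35 * min(diff(range(coords[, 1])), diff(range(coords[, 2])))
  ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 4
  seeds <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
  d2 <- outer(rowSums(coords^2), rowSums(seeds^2), "+") -
    2 * coords %*% t(seeds)
  max.col(-d2, ties.method = "first")
}

.synthetic_annotation <- function(n_chrom, genes_per_arm) {
  spacing <- 1e5
  cen <- (genes_per_arm + 0.5) * spacing
  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(
      gene_id = sprintf("g%s_%s%03d", ch, rep(c("p", "q"), each = genes_per_arm),
                        rep(seq_len(genes_per_arm), 2)),
      chrom = as.character(ch),
      start = c(seq_len(genes_per_arm) * spacing,
                cen + seq_len(genes_per_arm) * spacing),
      stringsAsFactors = FALSE
    )
  }))
  cyto <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(chrom = as.character(ch),
               start = c(0, cen - 1),  # 0-based band starts
               end = c(cen - 1, cen + (genes_per_arm + 1) * spacing),
               band = c("p11", "q11"), stringsAsFactors = FALSE)
  }))
  list(genes = genes, cytoband = cyto)
}

#' Simulate a spatial transcriptome with CNA ground truth
#'
#' Draws per-gene log-normal baselines, assigns each lattice spot to a
#' clone region, applies the clone's CNA segment folds multiplicatively,
#' scales by a per-spot library factor, and samples counts (negative
#' binomial by default) followed by binomial dropout thinning.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `cna_simulation`: list with `expr`
#'   ([spatial_expression]), `annotation`
#'   ([gene_annotation][load_gene_annotation]), `cytoband` (data frame),
#'   `truth` (list: `clone` per spot, 0 = normal; `states` spots x genes
#'   matrix over -1/0/1), and `config`.
#' @export
simulate_spatial_cna <- function(cfg = simulation_config()) {
  stopifnot(is(cfg, "simulation_config"))
  set.seed(cfg$seed)
  coords <- lattice_coords(cfg$grid[1], cfg$grid[2])
  n <- nrow(coords)
  region <- .voronoi_regions(coords, cfg$n_clones + 1) - 1L  # 0 = normal
  geno <- .synthetic_annotation(cfg$n_chrom, cfg$genes_per_arm)
  ann <- load_gene_annotation(geno$genes, geno$cytoband)
  m <- nrow(geno$genes)
  gene_ids <- geno$genes$gene_id

  # per-clone fold vector over genes, and the true state matrix
  folds <- matrix(1, cfg$n_clones + 1, m,
                  dimnames = list(NULL, gene_ids))
  states_clone <- matrix(0L, cfg$n_clones + 1, m,
                         dimnames = list(NULL, gene_ids))
  for (i in seq_len(nrow(cfg$segments))) {
    sg <- cfg$segments[i, ]
    on_arm <- ann$gene_id[ann$chrom == sg$chrom & ann$arm == sg$arm]
    idx <- ann$arm_index[match(on_arm, ann$gene_id)]
    hit <- on_arm[idx >= sg$start_gene & idx <= sg$end_gene]
    folds[sg$clone + 1, hit] <- sg$fold
    states_clone[sg$clone + 1, hit] <- sg$state
  }

  baseline <- rlnorm(m, cfg$baseline_meanlog, cfg$baseline_sdlog)
  lib <- rlnorm(n, 0, cfg$libsize_sdlog)
  mu <- (lib * folds[region + 1L, , drop = FALSE]) *
    rep(baseline, each = n)
  counts <- if (cfg$noise == "nb") {
    matrix(rnbinom(n * m, mu = mu, size = 1 / cfg$dispersion), n, m)
  } else {
    matrix(stats::rpois(n * m, mu), n, m)
  }
  if (cfg$dropout > 0)
    counts <- matrix(rbinom(n * m, counts, 1 - cfg$dropout), n, m)
  dimnames(counts) <- list(rownames(coords), gene_ids)

  truth_states <- states_clone[region + 1L, , drop = FALSE]
  rownames(truth_states) <- rownames(coords)
  structure(
    list(expr = spatial_expression(counts, data.frame(coords)),
         annotation = ann, cytoband = geno$cytoband,
         truth = list(clone = setNames(region, rownames(coords)),
                      states = truth_states),
         config = cfg),
    class = "cna_simulation"
  )
}

#' Write a simulation in the exact input formats the readers accept
#'
#' Writes dense counts TSV, coordinates TSV, a BED gene annotation, a
#' cytoband table, and the ground-truth clone/state tables.
#'
#' @param sim A [simulate_spatial_cna()] result.
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             coords = file.path(dir, "coords.tsv"),
             genes = file.path(dir, "genes.bed"),
             cytoband = file.path(dir, "cytoband.tsv"),
             clones = file.path(dir, "truth_clones.tsv"),
             states = file.path(dir, "truth_states.tsv"))
  write_spatial_expression(sim$expr, paths["counts"], paths["coords"])
  ann <- sim$annotation
  bed <- data.frame(chrom = ann$chrom, start = ann$start - 1,
                    end = ann$start, name = ann$gene_id)
  write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$cytoband, paths["cytoband"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(spot_id = names(sim$truth$clone),
                         clone = unname(sim$truth$clone)),
              paths["clones"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(spot_id = rownames(sim$truth$states),
                         sim$truth$states, check.names = FALSE),
              paths["states"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate observation sequences from a 3-state Gaussian HMM
#'
#' Markov-chain state paths with Gaussian emissions; the independent
#' generator used to validate [baum_welch()] and [viterbi()].
#'
#' @param params An [hmm_params] object.
#' @param n_seq Number of sequences.
#' @param length Length of each sequence.
#' @param seed RNG seed.
#' @return List with `sequences` (list of numeric vectors) and `paths`
#'   (list of integer state vectors over 1/2/3).
#' @export
simulate_hmm_sequences <- function(params, n_seq, length, seed = 1) {
  stopifnot(is(params, "hmm_params"))
  set.seed(seed)
  paths <- vector("list", n_seq)
  seqs <- vector("list", n_seq)
  for (s in seq_len(n_seq)) {
    st <- integer(length)
    st[1] <- sample.int(3, 1, prob = params$initial)
    for (t in seq_len(length - 1))
      st[t + 1] <- sample.int(3, 1, prob = params$transition[st[t], ])
    paths[[s]] <- st
    seqs[[s]] <- rnorm(length, params$mu[st], params$sigma[st])
  }
  list(sequences = seqs, paths = paths)
}

#' Simulate lattice point patterns
#'
#' Event spot sets on a lattice under three generating regimes:
#' complete spatial randomness (uniform without replacement), a
#' Matern-style clustered pattern (uniform parents, events drawn from
#' the union of parent neighbourhoods), and an inhibited pattern (greedy
#' minimum-distance thinning of a random order).
#'
#' @param kind `"csr"`, `"clustered"` or `"inhibited"`.
#' @param grid Lattice coordinates (matrix) or dimensions `c(rows,
#'   cols)`.
#' @param n_events Number of event spots.
#' @param param List: `n_parents` and `radius` for `"clustered"`
#'   (defaults 3 and 2); `min_dist` for `"inhibited"` (default 2);
#'   `retries` bounds the inhibition attempts (default 20).
#' @param seed RNG seed.
#' @return Integer vector of event spot indices into the lattice, with
#'   the lattice coordinates as attribute `coords`.
#' @export
simulate_point_patterns <- function(kind = c("csr", "clustered", "inhibited"),
                                    grid, n_events, param = list(),
                                    seed = 1) {
  kind <- match.arg(kind)
  coords <- if (is.matrix(grid)) grid else lattice_coords(grid[1], grid[2])
  n <- nrow(coords)
  if (n_events > n) stop("more events than lattice spots")
  set.seed(seed)
  idx <- switch(kind,
    csr = sample.int(n, n_events),
    clustered = {
      n_parents <- param$n_parents %||% 3
      radius <- param$radius %||% 2
      parents <- sample.int(n, n_parents)
      d2 <- outer(rowSums(coords^2), rowSums(coords[parents, , drop = FALSE]^2),
                  "+") - 2 * coords %*% t(coords[parents, , drop = FALSE])
      cand <- which(apply(d2 <= radius^2 + 1e-9, 1, any))
      if (length(cand) < n_events)
        stop("clustered pattern: not enough spots within the parent radius")
      sample(cand, n_events)
    },
    inhibited = {
      min_dist <- param$min_dist %||% 2
      retries <- param$retries %||% 20
      res <- NULL
      for (r in seq_len(retries)) {
        ord <- sample.int(n)
        acc <- integer(0)
        for (i in ord) {
          if (length(acc) == 0 ||
              all((coords[acc, 1] - coords[i, 1])^2 +
                  (coords[acc, 2] - coords[i, 2])^2 >= min_dist^2)) {
            acc <- c(acc, i)
            if (length(acc) == n_events) break
          }
        }
        if (length(acc) == n_events) { res <- acc; break }
      }
      if (is.null(res))
        stop("inhibited pattern infeasible at the requested minimum distance")
      res
    })
  structure(sort(idx), coords = coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
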