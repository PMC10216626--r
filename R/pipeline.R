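#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with the
#' package defaults. All randomness flows from the single `seed` through
#' fixed per-stage substreams.
#'
#' @param seed Top-level seed (default 1).
#' @param min_genes_per_spot,min_spots_per_gene,min_mean_expression
#'   Preprocessing filters, see [normalize_expression()].
#' @param k,W1,W2,radius,create_edges,self_loops Spot-graph settings, see
#'   [build_spot_graph()].
#' @param latent_dim,hidden_dim,decoder_hidden,embed_dim,epochs,lr,lambda1,lambda2,lambda3,bce_target
#'   VGAE settings, see [vgae_train()].
#' @param k_latent,resolution Louvain settings, see [louvain_cluster()].
#' @param windows,final_window,combine,fit_level,min_obs,min_delta,max_iter
#'   CNA-HMM settings, see [infer_cna()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            min_genes_per_spot = 200,
                            min_spots_per_gene = 3,
                            min_mean_expression = 1,
                            k = 15, W1 = 1, W2 = 1, radius = NULL,
                            create_edges = FALSE, self_loops = TRUE,
                            latent_dim = 32, hidden_dim = 128,
                            decoder_hidden = 128, embed_dim = 32,
                            epochs = 400, lr = 1e-3, lambda1 = NULL,
                            lambda2 = 1, lambda3 = 1,
                            bce_target = "binary",
                            k_latent = 50, resolution = 0.2,
                            windows = c(11, 31, 51), final_window = 5,
                            combine = "cascade", fit_level = "cluster",
                            min_obs = 500, min_delta = 0.2,
                            max_iter = 100) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full CNA inference pipeline
#'
#' Executes the stages in order: preprocessing, fused spot-graph
#' construction, VGAE embedding, Louvain clustering, and per-cluster
#' HMM CNA calling. Supplying `clusters` bypasses the VGAE and Louvain
#' stages and uses the given labels directly. With `out_dir` set, every
#' stage's outputs are written (normalized matrix, edge list, loss
#' trace, cluster table, CNA state matrices, per-cluster HMM parameters)
#' together with a manifest recording versions, seeds, parameters and
#' per-stage wall time. Two runs with the same configuration and seed
#' produce bit-identical CNA state matrices.
#'
#' @param expr A [spatial_expression] object.
#' @param annotation A [gene_annotation][load_gene_annotation] object.
#' @param config A [pipeline_config()].
#' @param clusters Optional precomputed cluster labels (bypasses the
#'   embedding and clustering stages).
#' @param reference_spots Optional reference/normal spot ids for
#'   centring.
#' @param normal_clusters Optional cluster labels set all-neutral in the
#'   CNA stage.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress (default `TRUE`).
#' @return List of class `cna_pipeline_result` with elements `norm`,
#'   `graph`, `vgae` (`NULL` when bypassed), `clusters`, `profile` and
#'   `manifest`.
#' @export
run_cna_pipeline <- function(expr, annotation, config = pipeline_config(),
                             clusters = NULL, reference_spots = NULL,
                             normal_clusters = NULL, out_dir = NULL,
                             verbose = TRUE) {
  stopifnot(is(expr, "spatial_expression"), is(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  clock <- function(stage, code) {
    t0 <- Sys.time()
    res <- force(code)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  say("[1/5] preprocessing (%d spots x %d genes)", nrow(expr$counts),
      ncol(expr$counts))
  norm <- clock("preprocess",
    normalize_expression(expr, config$min_genes_per_spot,
                         config$min_spots_per_gene,
                         config$min_mean_expression, reference_spots))

  say("[2/5] spot graph (k = %d)", config$k)
  graph <- clock("graph",
    build_spot_graph(norm$X, norm$coords,
                     k = min(config$k, nrow(norm$X) - 1), W1 = config$W1,
                     W2 = config$W2, radius = config$radius,
                     create_edges = config$create_edges,
                     self_loops = config$self_loops))

  fit <- NULL
  if (is.null(clusters)) {
    say("[3/5] VGAE embedding (%d epochs)", config$epochs)
    fit <- clock("vgae",
      vgae_train(norm$X, graph$A_norm, latent_dim = config$latent_dim,
                 hidden_dim = config$hidden_dim,
                 decoder_hidden = config$decoder_hidden,
                 embed_dim = config$embed_dim, epochs = config$epochs,
                 lr = config$lr, lambda1 = config$lambda1,
                 lambda2 = config$lambda2, lambda3 = config$lambda3,
                 bce_target = config$bce_target,
                 seed = stage_seed(config$seed, "vgae")))
    say("[4/5] Louvain clustering (resolution %.2f)", config$resolution)
    clusters <- clock("cluster",
      louvain_cluster(fit$latent$mu,
                      k_latent = min(config$k_latent,
                                     nrow(fit$latent$mu) - 1),
                      resolution = config$resolution,
                      seed = stage_seed(config$seed, "louvain")))
  } else {
    say("[3-4/5] embedding/clustering bypassed (clusters supplied)")
    clusters <- structure(
      list(labels = .as_cluster_labels(clusters, rownames(norm$X)),
           modularity = NA_real_,
           n_clusters = length(unique(.as_cluster_labels(clusters,
                                                         rownames(norm$X)))),
           params = list(supplied = TRUE)),
      class = "cluster_assignment")
  }

  say("[5/5] CNA inference (%d clusters)", clusters$n_clusters)
  profile <- clock("cna",
    infer_cna(norm, annotation, clusters, windows = config$windows,
              final_window = config$final_window, combine = config$combine,
              fit_level = config$fit_level, min_obs = config$min_obs,
              min_delta = config$min_delta,
              normal_clusters = normal_clusters,
              max_iter = config$max_iter))

  manifest <- list(
    package = "spotcna",
    version = as.character(utils::packageVersion("spotcna")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = list(vgae = stage_seed(config$seed, "vgae"),
                       louvain = stage_seed(config$seed, "louvain")),
    config = unclass(config),
    n_spots = nrow(norm$X), n_genes = ncol(norm$X),
    preprocess = norm$normalization_log[c("n_spots_removed",
                                          "n_genes_removed",
                                          "n_genes_below_cutoff")],
    n_clusters = clusters$n_clusters,
    timings_sec = as.list(timings)
  )

  result <- structure(
    list(norm = norm, graph = graph, vgae = fit, clusters = clusters,
         profile = profile, manifest = manifest),
    class = "cna_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write every pipeline output under one directory
#'
#' @param result A [run_cna_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nm <- data.frame(spot_id = rownames(result$norm$X), result$norm$X,
                   check.names = FALSE)
  write.table(nm, file.path(out_dir, "normalized.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_edge_list(result$graph, file.path(out_dir, "graph_edges.tsv"))
  if (!is.null(result$vgae)) {
    write.table(result$vgae$trace, file.path(out_dir, "loss_trace.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    mu <- data.frame(spot_id = rownames(result$vgae$latent$mu),
                     result$vgae$latent$mu, check.names = FALSE)
    write.table(mu, file.path(out_dir, "latent_mu.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_clusters(result$clusters, file.path(out_dir, "clusters.tsv"))
  write_cna_profile(result$profile, out_dir)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cna_pipeline_result <- function(x, ...) {
  cat(sprintf("cna_pipeline_result: %d spots, %d genes, %d clusters\n",
              x$manifest$n_spots, x$manifest$n_genes, x$manifest$n_clusters))
  print(x$profile)
  invisible(x)
}
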