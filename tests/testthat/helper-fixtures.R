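# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(5, 0, 2, 8,
                1, 3, 0, 4,
                7, 2, 9, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("gA", "gB", "gC", "gD")))
  m
}

tiny_coords <- function() {
  data.frame(spot_id = c("s1", "s2", "s3"), x = c(1, 2, 1), y = c(1, 1, 2))
}

tiny_expr <- function() spatial_expression(tiny_counts(), tiny_coords())

# 6-gene annotation on 2 chromosomes with a cytoband table whose
# centromeres start at 1000 (chr1) and 500 (chr2)
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    chrom = c("1", "1", "1", "2", "2", "2"),
    start = c(999, 1, 1000, 30, 600, 499)
  )
  cyto <- data.frame(
    chrom = c("1", "1", "2", "2"),
    start = c(0, 999, 0, 499),   # 0-based: centromeres at 1-based 1000/500
    end = c(999, 2000, 499, 1000),
    band = c("p11", "q11", "p11", "q11")
  )
  list(genes = genes, cyto = cyto)
}

# two well-separated Gaussian blobs in 2-D
blob_matrix <- function(n_per = 20, sep = 10, d = 2, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  rownames(x) <- sprintf("b%02d", seq_len(2 * n_per))
  x
}

# a small spatial simulation reused by slower integration tests
small_sim <- function(seed = 3) {
  simulate_spatial_cna(simulation_config(
    grid = c(14, 14), n_chrom = 4, genes_per_arm = 60, seed = seed))
}

small_config <- function(seed = 3) {
  pipeline_config(seed = seed, min_genes_per_spot = 50, epochs = 60,
                  hidden_dim = 64, decoder_hidden = 64, latent_dim = 16,
                  embed_dim = 16, k = 10, k_latent = 20,
                  windows = c(5, 11, 21), min_obs = 200)
}
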