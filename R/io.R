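#' Construct a spatial expression object
#'
#' Container for a spot-by-gene count matrix together with the 2-D array
#' coordinates of every spot. Rows are spots, columns are genes.
#'
#' @param counts Non-negative numeric matrix, spots x genes, with unique
#'   row (spot) and column (gene) names.
#' @param coords Data frame or matrix with one row per spot and columns
#'   `x` and `y` (array units); row order must match `counts`.
#' @return An object of class `spatial_expression` with elements `counts`,
#'   `spot_ids`, `gene_ids` and `coords` (two-column matrix).
#' @export
spatial_expression <- function(counts, coords) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have spot row names and gene column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate spot ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  coords <- as.matrix(as.data.frame(coords)[, c("x", "y")])
  if (nrow(coords) != nrow(counts))
    stop("coords must have one row per spot")
  storage.mode(coords) <- "double"
  rownames(coords) <- rownames(counts)
  structure(
    list(counts = counts, spot_ids = rownames(counts),
         gene_ids = colnames(counts), coords = coords),
    class = "spatial_expression"
  )
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat(sprintf("spatial_expression: %d spots x %d genes\n",
              length(x$spot_ids), length(x$gene_ids)))
  invisible(x)
}

#' @export
dim.spatial_expression <- function(x) dim(x$counts)

.read_table_auto <- function(path, ...) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

.read_coords <- function(coords_path) {
  coords <- .read_table_auto(coords_path)
  if (!all(c("spot_id", "x", "y") %in% names(coords))) {
    if (ncol(coords) < 3)
      stop("coordinates file needs columns spot_id, x, y")
    names(coords)[1:3] <- c("spot_id", "x", "y")
  }
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id))
    stop("duplicate spot ids in coordinates: ",
         paste(unique(coords$spot_id[duplicated(coords$spot_id)]),
               collapse = ", "))
  coords
}

.read_counts_matrix <- function(counts_path, features_path, barcodes_path) {
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    dir <- dirname(counts_path)
    if (is.null(barcodes_path)) {
      barcodes_path <- file.path(dir, "barcodes.tsv")
    }
    if (is.null(features_path)) {
      features_path <- file.path(dir, "features.tsv")
      if (!file.exists(features_path))
        features_path <- file.path(dir, "genes.tsv")
    }
    if (!file.exists(barcodes_path) || !file.exists(features_path))
      stop("MatrixMarket input needs barcodes and features sidecar files")
    barcodes <- read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    features <- read.delim(features_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
      dimnames(m) <- list(features, barcodes)  # genes x spots convention
    } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
      dimnames(m) <- list(barcodes, features)
    } else {
      stop("matrix dimensions do not match barcodes/features sidecars")
    }
    m
  } else {
    df <- .read_table_auto(counts_path, row.names = 1)
    as.matrix(df)
  }
}

#' Read spatial expression data from disk
#'
#' Reads a count matrix (MatrixMarket `.mtx` with barcodes/features
#' sidecars, or a dense TSV/CSV with row and column names) and a spot
#' coordinate table, aligns them on shared spot ids, and resolves the
#' matrix orientation so that rows are spots. Orientation is detected by
#' overlap between the matrix dimnames and the coordinate spot ids.
#'
#' @param counts_path Path to the count matrix.
#' @param coords_path Path to a TSV/CSV with columns `spot_id`, `x`, `y`.
#' @param features_path,barcodes_path Optional sidecar paths for `.mtx`
#'   input; default to `features.tsv`/`genes.tsv` and `barcodes.tsv`
#'   next to the matrix.
#' @return A [spatial_expression] object containing the spots present in
#'   both files (ordered as in the coordinates file). Spots present in
#'   only one file are dropped with a warning.
#' @export
read_spatial_expression <- function(counts_path, coords_path,
                                    features_path = NULL,
                                    barcodes_path = NULL) {
  coords <- .read_coords(coords_path)
  m <- .read_counts_matrix(counts_path, features_path, barcodes_path)
  ov_rows <- length(intersect(rownames(m), coords$spot_id))
  ov_cols <- length(intersect(colnames(m), coords$spot_id))
  if (ov_rows == 0 && ov_cols == 0)
    stop("no overlapping spot ids between counts and coordinates")
  if (ov_cols > ov_rows) m <- t(m)
  common <- coords$spot_id[coords$spot_id %in% rownames(m)]
  n_drop <- (nrow(m) - length(common)) + (nrow(coords) - length(common))
  if (n_drop > 0)
    warning(sprintf("dropping %d spot(s) not present in both files", n_drop))
  m <- m[common, , drop = FALSE]
  coords <- coords[match(common, coords$spot_id), , drop = FALSE]
  spatial_expression(m, coords)
}

#' Write spatial expression data as dense TSV
#'
#' Inverse of [read_spatial_expression()] for the dense-TSV format;
#' integer counts round-trip bit-exactly.
#'
#' @param x A [spatial_expression] object.
#' @param counts_path,coords_path Output paths.
#' @export
write_spatial_expression <- function(x, counts_path, coords_path) {
  df <- data.frame(spot_id = x$spot_ids, x$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- data.frame(spot_id = x$spot_ids, x = x$coords[, "x"],
                   y = x$coords[, "y"])
  write.table(cd, coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Filter, scale and centre a spatial count matrix
#'
#' Preprocessing for expression-based CNA inference: low-coverage spots and
#' rarely detected genes are removed, each spot is library-size scaled to
#' the median library size, counts are `log1p`-transformed, and each gene
#' is centred by subtracting its median over the reference spots (all spots
#' when no reference is given). After centring, copy-neutral genes
#' fluctuate around zero, the baseline the downstream HMM assumes.
#'
#' @param raw A [spatial_expression] object.
#' @param min_genes_per_spot Minimum number of detected (count > 0) genes a
#'   spot must have to be kept (default 200; spot filtering is applied
#'   first, over the full gene set).
#' @param min_spots_per_gene Minimum number of retained spots a gene must
#'   be detected in to be kept (default 3).
#' @param min_mean_expression Minimum per-gene mean of the library-scaled
#'   counts (default 1). Genes below this carry mostly sampling noise and
#'   discreteness artefacts (their median count is typically 0, which
#'   would create a point mass at exactly 0 after centring) and are
#'   excluded from CNA inference, the usual expression cutoff of
#'   expression-based CNA tools. Set to 0 to keep every detected gene.
#' @param reference_spots Optional character vector of spot ids treated as
#'   copy-neutral reference; per-gene medians are computed over these.
#' @return An object of class `normalized_expression` with elements `X`
#'   (spots x genes matrix), `coords` (for the retained spots) and
#'   `normalization_log`.
#' @export
normalize_expression <- function(raw, min_genes_per_spot = 200,
                                 min_spots_per_gene = 3,
                                 min_mean_expression = 1,
                                 reference_spots = NULL) {
  stopifnot(is(raw, "spatial_expression"),
            min_genes_per_spot >= 0, min_spots_per_gene >= 0,
            min_mean_expression >= 0)
  if (!is.null(reference_spots) &&
      !all(reference_spots %in% raw$spot_ids))
    stop("reference_spots must be a subset of spot ids")
  counts <- raw$counts
  detected <- counts > 0
  keep_spot <- rowSums(detected) >= min_genes_per_spot
  if (!any(keep_spot)) stop("all spots removed by filtering")
  counts <- counts[keep_spot, , drop = FALSE]
  keep_gene <- colSums(counts > 0) >= min_spots_per_gene
  if (!any(keep_gene)) stop("all genes removed by filtering")
  counts <- counts[, keep_gene, drop = FALSE]

  lib <- rowSums(counts)
  scale_f <- median(lib) / lib
  scale_f[!is.finite(scale_f)] <- 0
  scaled <- counts * scale_f
  keep_expr <- colMeans(scaled) >= min_mean_expression
  if (!any(keep_expr)) stop("all genes removed by the expression cutoff")
  n_low <- sum(!keep_expr)
  scaled <- scaled[, keep_expr, drop = FALSE]
  X <- log1p(scaled)

  ref <- rownames(X)
  if (!is.null(reference_spots)) {
    ref <- intersect(reference_spots, rownames(X))
    if (length(ref) == 0)
      stop("no reference spots survived filtering")
  }
  centers <- apply(X[ref, , drop = FALSE], 2, median)
  X <- sweep(X, 2, centers)
  stopifnot(all(is.finite(X)))

  structure(
    list(
      X = X,
      coords = raw$coords[keep_spot, , drop = FALSE],
      normalization_log = list(
        steps = c("filter", "library-size scale to median",
                  "expression cutoff", "log1p", "median-centre per gene"),
        n_spots_removed = sum(!keep_spot),
        n_genes_removed = sum(!keep_gene) + n_low,
        n_genes_below_cutoff = n_low,
        reference = if (is.null(reference_spots)) "all spots" else ref
      )
    ),
    class = "normalized_expression"
  )
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d spots x %d genes (removed %d spots, %d genes)\n",
              nrow(x$X), ncol(x$X), x$normalization_log$n_spots_removed,
              x$normalization_log$n_genes_removed))
  invisible(x)
}
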