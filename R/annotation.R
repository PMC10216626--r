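# chromosome order helper: numeric chromosomes first in numeric order, then
# the rest alphabetically (X, Y, MT, ...)
.chrom_order <- function(chroms) {
  stripped <- sub("^chr", "", chroms)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

.read_cytoband <- function(cytoband_path) {
  first <- readLines(cytoband_path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  cb <- read.delim(cytoband_path, header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(cb) < 4) stop("cytoband table needs chrom, start, end, band")
  names(cb)[1:4] <- c("chrom", "start", "end", "band")
  cb$chrom <- as.character(cb$chrom)
  cb
}

.read_bed_genes <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (grepl("^(track|browser|#)", first)) 1 else 0
  bed <- read.delim(path, header = FALSE, skip = skip,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED gene annotation needs >= 4 columns")
  # BED starts are 0-based half-open
  data.frame(gene_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             start = as.numeric(bed[[2]]) + 1, stringsAsFactors = FALSE)
}

.read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF annotation requires the rtracklayer package")
  df <- as.data.frame(rtracklayer::import(path))
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  ids <- if ("gene_id" %in% names(df)) df$gene_id
         else as.character(seq_len(nrow(df)))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(df$seqnames),
             start = df$start, stringsAsFactors = FALSE)
}

#' Load a gene annotation and assign chromosome arms
#'
#' Maps every gene to (chromosome, arm, start) and ranks genes along each
#' arm by genomic start position. Arms are assigned from a UCSC-style
#' cytoband table: the centromere start of a chromosome is the smallest
#' start among its q bands, and a gene belongs to the p arm iff its
#' (1-based) start lies strictly before the centromere start (half-open
#' convention: a gene starting exactly at the centromere start is q).
#' Genes on chromosomes absent from the cytoband table (unplaced contigs)
#' are dropped with a message.
#'
#' @param annotation_path Path to a GTF/GFF (gene features; parsed with
#'   rtracklayer) or a 4+-column BED (chrom, 0-based start, end, gene id),
#'   or a data frame with columns `gene_id`, `chrom`, `start` (1-based).
#' @param cytoband_path Path to a cytoband table (chrom, 0-based band
#'   start, band end, band name; UCSC `cytoBand.txt` layout, with or
#'   without header), or an equivalent data frame.
#' @return An object of class `gene_annotation`: a data frame with columns
#'   `gene_id`, `chrom`, `arm`, `start`, `arm_index` (rank within the
#'   (chromosome, arm); ties in start broken by gene id). The number of
#'   dropped genes is stored in `attr(, "n_dropped_unplaced")`.
#' @export
load_gene_annotation <- function(annotation_path, cytoband_path) {
  genes <- if (is.data.frame(annotation_path)) {
    stopifnot(all(c("gene_id", "chrom", "start") %in% names(annotation_path)))
    annotation_path[, c("gene_id", "chrom", "start")]
  } else if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", annotation_path,
                   ignore.case = TRUE)) {
    .read_gtf_genes(annotation_path)
  } else {
    .read_bed_genes(annotation_path)
  }
  cb <- if (is.data.frame(cytoband_path)) {
    stopifnot(all(c("chrom", "start", "band") %in% names(cytoband_path)))
    cytoband_path
  } else {
    .read_cytoband(cytoband_path)
  }

  # centromere start per chromosome, 1-based: first q band start
  cen <- vapply(split(cb, cb$chrom), function(d) {
    qs <- d$start[grepl("^q", d$band)]
    if (length(qs) == 0) Inf else min(qs) + 1
  }, numeric(1))

  placed <- genes$chrom %in% names(cen)
  n_dropped <- sum(!placed)
  if (n_dropped > 0)
    message(sprintf("dropping %d gene(s) on contigs absent from the cytoband table",
                    n_dropped))
  genes <- genes[placed, , drop = FALSE]
  if (nrow(genes) == 0) stop("zero genes annotated")
  if (anyDuplicated(genes$gene_id)) {
    genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  }

  genes$arm <- ifelse(genes$start < cen[genes$chrom], "p", "q")
  ord <- order(genes$chrom, genes$arm, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  key <- paste0(genes$chrom, genes$arm)
  genes$arm_index <- stats::ave(seq_len(nrow(genes)), key,
                                FUN = seq_along)
  rownames(genes) <- NULL
  structure(genes[, c("gene_id", "chrom", "arm", "start", "arm_index")],
            class = c("gene_annotation", "data.frame"),
            n_dropped_unplaced = n_dropped)
}

#' Order genes of a normalized matrix along chromosome arms
#'
#' Treats the p and q arm of every chromosome as an independent sequence:
#' for each (chromosome, arm) with at least one annotated gene present in
#' the matrix, records the gene ids and matrix column indices in ascending
#' genomic-start order (ties broken by gene id). Concatenating all arm
#' sequences of a spot recovers a permutation of that spot's gene vector.
#' Genes without annotation are excluded with a message.
#'
#' @param norm A `normalized_expression` object (or any matrix with gene
#'   column names).
#' @param ann A [gene_annotation][load_gene_annotation] object.
#' @return An object of class `arm_sequences`: list with `arms` (named
#'   list keyed e.g. `"1p"`, each with `chrom`, `arm`, `gene_ids`, `cols`)
#'   and `gene_ids` (the annotated genes, in matrix column order).
#' @export
build_arm_sequences <- function(norm, ann) {
  X <- if (is(norm, "normalized_expression")) norm$X else as.matrix(norm)
  stopifnot(is(ann, "gene_annotation"))
  present <- colnames(X) %in% ann$gene_id
  if (!any(present)) stop("no annotated genes present in the matrix")
  if (any(!present))
    message(sprintf("excluding %d unannotated gene(s) from arm sequences",
                    sum(!present)))
  ann <- ann[ann$gene_id %in% colnames(X), , drop = FALSE]
  keys <- paste0(ann$chrom, ann$arm)
  uniq_chrom <- unique(ann$chrom)[.chrom_order(unique(ann$chrom))]
  key_levels <- as.vector(t(outer(uniq_chrom, c("p", "q"), paste0)))
  key_levels <- key_levels[key_levels %in% keys]
  arms <- lapply(key_levels, function(k) {
    d <- ann[keys == k, , drop = FALSE]
    d <- d[order(d$start, d$gene_id), , drop = FALSE]
    list(key = k, chrom = d$chrom[1], arm = d$arm[1],
         gene_ids = d$gene_id, cols = match(d$gene_id, colnames(X)))
  })
  names(arms) <- key_levels
  structure(list(arms = arms, gene_ids = colnames(X)[present]),
            class = "arm_sequences")
}

#' Extract the ordered arm sequences of one spot
#'
#' @param X Spots x genes matrix (e.g. `norm$X`).
#' @param arms An [arm_sequences][build_arm_sequences] object.
#' @param spot Spot id or row index.
#' @return Named list (one element per arm) of numeric vectors ordered by
#'   genomic start, with gene ids as names.
#' @export
spot_arm_sequences <- function(X, arms, spot) {
  lapply(arms$arms, function(a)
    setNames(X[spot, a$cols], a$gene_ids))
}

#' @export
print.arm_sequences <- function(x, ...) {
  cat(sprintf("arm_sequences: %d arms, %d genes (%s)\n",
              length(x$arms), length(x$gene_ids),
              paste(utils::head(names(x$arms), 8), collapse = ", ")))
  invisible(x)
}
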