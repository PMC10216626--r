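test_that("arm assignment follows the half-open centromere convention", {
  ann <- load_gene_annotation(toy_annotation()$genes, toy_annotation()$cyto)
  arm <- setNames(ann$arm, ann$gene_id)
  expect_equal(arm[["gB"]], "p")   # start 1, centromere 1000
  expect_equal(arm[["gA"]], "p")   # start 999 < 1000
  expect_equal(arm[["gC"]], "q")   # start exactly at the centromere start
  expect_equal(arm[["gD"]], "p")   # chr2, centromere 500
  expect_equal(arm[["gF"]], "p")   # 499 < 500
  expect_equal(arm[["gE"]], "q")
})

test_that("ordering indices rank start positions within each arm", {
  ann <- load_gene_annotation(toy_annotation()$genes, toy_annotation()$cyto)
  for (key in unique(paste0(ann$chrom, ann$arm))) {
    d <- ann[paste0(ann$chrom, ann$arm) == key, ]
    expect_equal(d$arm_index[order(d$start, d$gene_id)],
                 seq_len(nrow(d)), info = key)
  }
})

test_that("ties in start position break lexicographically by gene id", {
  genes <- data.frame(gene_id = c("zz", "aa", "mm"), chrom = "1",
                      start = c(10, 10, 10))
  ann <- load_gene_annotation(genes, toy_annotation()$cyto)
  expect_equal(ann$gene_id[order(ann$arm_index)], c("aa", "mm", "zz"))
})

test_that("genes on unplaced contigs are dropped, zero genes is an error", {
  genes <- rbind(toy_annotation()$genes,
                 data.frame(gene_id = "gX", chrom = "scaffold_7", start = 5))
  expect_message(ann <- load_gene_annotation(genes, toy_annotation()$cyto),
                 "dropping 1 gene")
  expect_false("gX" %in% ann$gene_id)
  expect_equal(attr(ann, "n_dropped_unplaced"), 1)
  only_bad <- data.frame(gene_id = "gX", chrom = "scaffold_7", start = 5)
  expect_error(suppressMessages(
    load_gene_annotation(only_bad, toy_annotation()$cyto)), "zero genes")
})

test_that("BED input round-trips through the 0-based start convention", {
  ta <- toy_annotation()
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  write.table(data.frame(ta$genes$chrom, ta$genes$start - 1,
                         ta$genes$start, ta$genes$gene_id),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  cyt <- file.path(dir, "cyto.tsv")
  write.table(ta$cyto, cyt, sep = "\t", quote = FALSE, row.names = FALSE)
  from_files <- load_gene_annotation(bed, cyt)
  from_frames <- load_gene_annotation(ta$genes, ta$cyto)
  expect_equal(from_files, from_frames, ignore_attr = TRUE)
})

test_that("GTF gene features parse to the same annotation as data frames", {
  ta <- toy_annotation()
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "genes.gtf")
  writeLines(sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\";",
                     ta$genes$chrom, ta$genes$start, ta$genes$start + 100,
                     ta$genes$gene_id), gtf)
  ann <- load_gene_annotation(gtf, ta$cyto)
  ref <- load_gene_annotation(ta$genes, ta$cyto)
  expect_equal(ann[order(ann$gene_id), c("gene_id", "chrom", "arm", "start")],
               ref[order(ref$gene_id), c("gene_id", "chrom", "arm", "start")],
               ignore_attr = TRUE)
})

test_that("arm sequences are sorted by start and conserve each spot's values", {
  ta <- toy_annotation()
  ann <- load_gene_annotation(ta$genes, ta$cyto)
  set.seed(1)
  X <- matrix(rnorm(18), 3, 6,
              dimnames = list(paste0("s", 1:3),
                              c("gD", "gA", "gF", "gC", "gB", "gE")))
  arms <- build_arm_sequences(X, ann)
  expect_equal(names(arms$arms), c("1p", "1q", "2p", "2q"))
  expect_equal(arms$arms[["1p"]]$gene_ids, c("gB", "gA"))  # starts 1, 999
  expect_equal(arms$arms[["2p"]]$gene_ids, c("gD", "gF"))
  s2 <- spot_arm_sequences(X, arms, "s2")
  expect_equal(unname(s2[["1p"]]), unname(X["s2", c("gB", "gA")]))
  # conservation: all arm values of a spot are a permutation of its row
  expect_equal(sort(unname(unlist(s2))), sort(unname(X["s2", ])))
})

test_that("arm ordering is invariant to input gene column order", {
  ta <- toy_annotation()
  ann <- load_gene_annotation(ta$genes, ta$cyto)
  set.seed(2)
  X <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("s1", "s2"), ta$genes$gene_id))
  perm <- X[, sample(ncol(X))]
  a1 <- build_arm_sequences(X, ann)
  a2 <- build_arm_sequences(perm, ann)
  for (k in names(a1$arms)) {
    expect_equal(a1$arms[[k]]$gene_ids, a2$arms[[k]]$gene_ids)
    expect_equal(X[, a1$arms[[k]]$cols, drop = FALSE],
                 perm[, a2$arms[[k]]$cols, drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("a single-arm matrix yields exactly one arm sequence", {
  ann <- load_gene_annotation(
    data.frame(gene_id = c("g1", "g2"), chrom = "1", start = c(5, 2)),
    toy_annotation()$cyto)
  X <- matrix(1:2, 1, 2, dimnames = list("s1", c("g1", "g2")))
  arms <- build_arm_sequences(X, ann)
  expect_length(arms$arms, 1)
  expect_equal(arms$arms[["1p"]]$gene_ids, c("g2", "g1"))
})
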