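test_that("simulation is seed-deterministic and regions partition the grid", {
  a <- simulate_spatial_cna(simulation_config(grid = c(8, 8), seed = 5,
                                              n_chrom = 2,
                                              genes_per_arm = 30))
  b <- simulate_spatial_cna(simulation_config(grid = c(8, 8), seed = 5,
                                              n_chrom = 2,
                                              genes_per_arm = 30))
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$truth$states, b$truth$states)
  expect_setequal(unique(a$truth$clone), 0:3)
  expect_length(a$truth$clone, 64)
})

test_that("no segments means an all-neutral ground truth", {
  cfg <- simulation_config(grid = c(6, 6), n_chrom = 2, genes_per_arm = 20,
                           seed = 2)
  cfg$segments <- cfg$segments[0, ]
  sim <- simulate_spatial_cna(cfg)
  expect_true(all(sim$truth$states == 0))
})

test_that("amplified arms show the configured fold in mean expression", {
  sim <- simulate_spatial_cna(simulation_config(seed = 12))
  ann <- sim$annotation
  seg <- sim$config$segments
  amp <- seg[seg$state == 1L, ][1, ]  # clone 1, an amplified arm
  genes <- ann$gene_id[ann$chrom == amp$chrom & ann$arm == amp$arm]
  in_clone <- sim$truth$clone == amp$clone
  neutral <- sim$truth$clone == 0
  ratio <- mean(sim$expr$counts[in_clone, genes]) /
    mean(sim$expr$counts[neutral, genes])
  expect_equal(ratio, amp$fold, tolerance = 0.1)
  del <- seg[seg$state == -1L, ][1, ]
  genes_d <- ann$gene_id[ann$chrom == del$chrom & ann$arm == del$arm]
  ratio_d <- mean(sim$expr$counts[sim$truth$clone == del$clone, genes_d]) /
    mean(sim$expr$counts[neutral, genes_d])
  expect_equal(ratio_d, del$fold, tolerance = 0.1)
})

test_that("overlapping segments within a clone are rejected", {
  seg <- data.frame(clone = c(1, 1), chrom = "1", arm = "p",
                    state = c(-1L, 1L), fold = c(0.5, 1.5),
                    start_gene = c(1, 50), end_gene = c(60, 100))
  expect_error(simulation_config(segments = seg), "overlapping")
  seg2 <- transform(seg, end_gene = c(49, 100))
  expect_s3_class(simulation_config(segments = seg2), "simulation_config")
  expect_error(simulation_config(segments = transform(seg2, fold = c(1.2, 1.5))),
               "fold")
})

test_that("written simulations run back through the file readers", {
  sim <- simulate_spatial_cna(simulation_config(grid = c(6, 6), n_chrom = 2,
                                                genes_per_arm = 25,
                                                seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expr <- read_spatial_expression(paths["counts"], paths["coords"])
  expect_identical(expr$counts, sim$expr$counts)
  ann <- load_gene_annotation(paths["genes"], paths["cytoband"])
  expect_equal(ann$arm, sim$annotation$arm)
  expect_equal(ann$arm_index, sim$annotation$arm_index)
})

test_that("HMM sequence simulation matches its generating law", {
  tm <- matrix(c(0.9, 0.05, 0.05,
                 0.1, 0.8, 0.1,
                 0.05, 0.05, 0.9), 3, 3, byrow = TRUE)
  p <- hmm_params(tm, c(0.3, 0.4, 0.3), c(-1, 0, 1), c(0.3, 0.3, 0.3))
  sim <- simulate_hmm_sequences(p, 20, 5000, seed = 8)
  states <- unlist(sim$paths)
  trans <- table(head(states, -1), tail(states, -1))
  # drop cross-sequence transitions: rebuild per sequence
  trans <- matrix(0, 3, 3)
  for (pth in sim$paths)
    for (t in seq_len(length(pth) - 1))
      trans[pth[t], pth[t + 1]] <- trans[pth[t], pth[t + 1]] + 1
  freq <- trans / rowSums(trans)
  expect_true(all(abs(freq - tm) <= 0.01))
  x <- unlist(sim$sequences)
  for (k in 1:3) {
    xs <- x[states == k]
    expect_lt(abs(mean(xs) - p$mu[k]), 3 * 0.3 / sqrt(length(xs)) + 0.01)
  }
  # degenerate chain stays in its start state
  id <- hmm_params(diag(3), c(0, 1, 0), c(-1, 0, 1), rep(0.1, 3))
  sim2 <- simulate_hmm_sequences(id, 5, 50, seed = 9)
  expect_true(all(unlist(sim2$paths) == 2))
})

test_that("point patterns satisfy their defining constraints", {
  full <- simulate_point_patterns("csr", c(5, 5), 25, seed = 1)
  expect_setequal(as.integer(full), 1:25)
  co <- lattice_coords(15, 15)
  cl <- simulate_point_patterns("clustered", c(15, 15), 12,
                                param = list(n_parents = 1, radius = 2),
                                seed = 2)
  # reconstruct the parent: all events within distance 2 of some point
  d <- as.matrix(dist(co))[as.integer(cl), as.integer(cl)]
  expect_lte(max(d), 4 + 1e-9)  # diameter of a radius-2 disc
  inh <- simulate_point_patterns("inhibited", c(15, 15), 30,
                                 param = list(min_dist = 2), seed = 3)
  di <- dist(co[as.integer(inh), ])
  expect_gte(min(di), 2)
  expect_error(simulate_point_patterns("inhibited", c(4, 4), 16,
                                       param = list(min_dist = 3), seed = 4),
               "infeasible")
  expect_error(simulate_point_patterns("csr", c(3, 3), 10), "more events")
})
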