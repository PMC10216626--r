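test_that("event tables apply the frequency threshold with >= on the ceiling", {
  states <- matrix(0L, 50, 3, dimnames = list(sprintf("s%02d", 1:50),
                                              c("g1", "g2", "g3")))
  states[1:3, "g1"] <- 1L    # 3/50 with ceiling(0.05 * 50) = 3 -> included
  states[1:2, "g2"] <- 1L    # 2/50 -> excluded
  states[1:10, "g3"] <- -1L  # deletion event
  et <- cna_event_table(states, clusters = rep(0, 50), min_freq = 0.05)
  expect_setequal(colnames(et[["0"]]$events), c("g1-amp", "g3-del"))
  expect_equal(colSums(et[["0"]]$events)[c("g1-amp", "g3-del")],
               c("g1-amp" = 3, "g3-del" = 10))
  # all-neutral profile: no events at all
  et0 <- cna_event_table(matrix(0L, 10, 2,
                                dimnames = list(paste0("s", 1:10),
                                                c("a", "b"))),
                         clusters = rep(1, 10))
  expect_equal(ncol(et0[["1"]]$events), 0)
})

test_that("Fisher one-sided p-values match the hypergeometric tail oracle", {
  a <- c(rep(TRUE, 5), rep(FALSE, 15))
  res <- cooccurrence_test(a, a)
  want <- oracle_fisher_onesided(5, 0, 0, 15)
  expect_equal(res$p_cooccur, want$greater, tolerance = 1e-10)
  expect_equal(res$direction, "co-occurrence")
  expect_equal(res$p_cooccur, 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint supports covering all spots: minimal mutual-exclusion p
  b <- !a
  res2 <- cooccurrence_test(a, b)
  want2 <- oracle_fisher_onesided(0, 5, 15, 0)
  expect_equal(res2$p_mutex, want2$less, tolerance = 1e-10)
  expect_equal(res2$direction, "mutual-exclusion")
  # random tables
  set.seed(29)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    x <- runif(n) < runif(1, 0.2, 0.8)
    y <- runif(n) < runif(1, 0.2, 0.8)
    if (all(x) || !any(x) || all(y) || !any(y)) next
    got <- cooccurrence_test(x, y)
    want <- oracle_fisher_onesided(got$n11, got$n10, got$n01, got$n00)
    expect_equal(got$p_cooccur, want$greater, tolerance = 1e-10)
    expect_equal(got$p_mutex, want$less, tolerance = 1e-10)
  }
})

test_that("degenerate margins are flagged untestable", {
  res <- cooccurrence_test(rep(TRUE, 8), c(TRUE, rep(FALSE, 7)))
  expect_equal(res$direction, "untestable")
  expect_true(is.na(res$p))
})

test_that("independent events rarely reach significance (null calibration)", {
  set.seed(30)
  hits <- 0
  for (rep in 1:1000) {
    x <- runif(30) < 0.4
    y <- runif(30) < 0.4
    if (all(x) || !any(x) || all(y) || !any(y)) next
    p <- cooccurrence_test(x, y)$p
    if (p <= 0.05) hits <- hits + 1
  }
  expect_lt(hits / 1000, 0.1)
})

test_that("BH q-values match a direct step-up implementation", {
  set.seed(31)
  states <- matrix(sample(c(-1L, 0L, 1L), 40 * 6, replace = TRUE,
                          prob = c(0.2, 0.6, 0.2)), 40, 6,
                   dimnames = list(sprintf("s%02d", 1:40), paste0("g", 1:6)))
  et <- cna_event_table(states, clusters = rep(1, 40), min_freq = 0.05)
  res <- cooccurrence_analysis(et)
  ok <- res$direction != "untestable"
  expect_equal(res$q[ok], oracle_bh(res$p[ok]))
  expect_true(all(res$q[ok] >= res$p[ok]))
  o <- order(res$p[ok])
  expect_true(all(diff(res$q[ok][o]) >= -1e-12))
})

test_that("differential CNA matches the one-sided Fisher oracle", {
  set.seed(32)
  states <- matrix(sample(c(-1L, 0L, 1L), 60 * 8, replace = TRUE,
                          prob = c(0.15, 0.7, 0.15)), 60, 8,
                   dimnames = list(sprintf("s%02d", 1:60), paste0("g", 1:8)))
  labels <- rep(c(0, 1, 2), each = 20)
  res <- differential_cna(states, labels, normal_cluster = 0)
  for (r in sample(nrow(res), 30)) {
    row <- res[r, ]
    tab <- matrix(c(row$n_event_cluster,
                    row$n_cluster - row$n_event_cluster,
                    row$n_event_normal,
                    row$n_normal - row$n_event_normal), 2, 2)
    expect_equal(row$p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  # extremes: identical frequencies ~ p 1; total enrichment ~ max score
  st2 <- matrix(0L, 40, 2, dimnames = list(sprintf("s%02d", 1:40),
                                           c("flat", "hot")))
  st2[1:20, "hot"] <- 1L            # all tumour spots amplified
  st2[c(1:5, 21:25), "flat"] <- -1L # same deletion rate in both groups
  res2 <- differential_cna(st2, rep(c(1, 0), each = 20), normal_cluster = 0)
  hot <- res2[res2$gene == "hot" & res2$state == "amplification", ]
  flat <- res2[res2$gene == "flat" & res2$state == "deletion", ]
  expect_equal(hot$p, 1 / choose(40, 20), tolerance = 1e-10)
  expect_gt(flat$p, 0.5)
  expect_lt(abs(flat$score), 0.31)
  expect_gt(hot$score, 10)
})
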