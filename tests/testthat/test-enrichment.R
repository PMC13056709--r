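ranked_fixture <- function(n = 10, seed = 33) {
  withr::local_seed(seed)
  stats <- sort(rnorm(n), decreasing = TRUE)
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)), stat = stats)
}

test_that("temporal DE contrasts day 14 against day 0 within one type", {
  exp <- tiny_experiment(seed = 34, drift_sd = 0.4)
  de <- temporal_de(exp, cell_type = "Astrocyte", min_cells = 10)
  expect_true(all(c("log2fc", "p_adj") %in% names(de)))

  # swapping the timepoints negates the fold changes
  swapped_cells <- exp$cells
  swapped_cells$timepoint <- ifelse(swapped_cells$timepoint == "day0",
                                    "day14", "day0")
  de_sw <- temporal_de(cbind(exp$counts_day0, exp$counts_day14),
                       swapped_cells, cell_type = "Astrocyte",
                       min_cells = 10)
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-12)

  expect_error(
    temporal_de(exp, cell_type = "Astrocyte", min_cells = 1e5), "cells at")
})

test_that("zero-drift copies give a near-null temporal contrast", {
  exp <- copy_day0_as_day14(tiny_experiment(seed = 35))
  de <- temporal_de(exp, cell_type = "Neuron", min_cells = 10)
  # literal copies: identical group sums up to depth, expect no BH hits
  expect_lte(sum(de$significant), 2)
})

test_that("rank_statistic sorts by log2fc with lexicographic ties", {
  de <- tibble::tibble(gene_id = c("b", "a", "c", "d"),
                       log2fc = c(1, 2, 1, -3))
  got <- rank_statistic(de)
  expect_equal(got$gene_id, c("a", "b", "c", "d"))
  expect_equal(got$stat, c(2, 1, 1, -3))
  # negating reverses the order up to the tie block
  neg <- rank_statistic(dplyr::mutate(de, log2fc = -log2fc))
  expect_equal(neg$gene_id, c("d", "b", "c", "a"))
  expect_error(rank_statistic(de[0, ]), "Empty")
})

test_that("the enrichment score matches the hand-stepped running sum", {
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                           stat = rep(2, 10))
  # set = top 3 with equal weights: running max is 1 at position 3
  es <- enrichment_score(ranked, sprintf("g%02d", 1:3))
  expect_equal(es$es, 1)
  expect_equal(es$running$running_sum[3], 1)
  expect_equal(es$running$running_sum[10], 0, tolerance = 1e-12)

  # bottom-of-list set scores negative
  es_low <- enrichment_score(ranked_fixture(20), sprintf("g%03d", 17:20))
  expect_lt(es_low$es, 0)

  withr::local_seed(36)
  for (i in 1:20) {
    rk <- ranked_fixture(50, seed = 100 + i)
    set <- sample(rk$gene_id, sample(3:20, 1))
    es_i <- enrichment_score(rk, set)$es
    expect_equal(es_i, oracle_es(setNames(rk$stat, rk$gene_id), set),
                 tolerance = 1e-12)
    expect_lte(abs(es_i), 1)
  }
  expect_error(enrichment_score(ranked_fixture(10), "absent"), "intersect")
})

test_that("the fast positional ES used for permutations agrees with the full walk", {
  withr::local_seed(37)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    stats <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(stats) <- sprintf("g%04d", seq_len(n))
    set <- sample(names(stats), sample(1:(n - 1), 1))
    expect_equal(preservatr:::es_from_positions(
      sort(which(names(stats) %in% set)), abs(stats), n),
      enrichment_score(stats, set)$es,
      tolerance = 1e-12)
  }
})

test_that("the enrichment score agrees with an external GSEA implementation", {
  skip_if_not_installed("fgsea")
  withr::local_seed(38)
  for (i in 1:10) {
    n <- 150
    stats <- sort(rnorm(n, sd = 1.5), decreasing = TRUE)
    names(stats) <- sprintf("g%04d", seq_len(n))
    set <- sample(names(stats), 20)
    ours <- enrichment_score(stats, set)$es
    theirs <- fgsea::calcGseaStat(stats, which(names(stats) %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("gsea is deterministic in the seed and bounds its permutation p-values", {
  rk <- ranked_fixture(300, seed = 39)
  sets <- synthetic_gene_sets(rk$gene_id, n_sets = 8, size_range = c(10, 40),
                              seed = 40)
  a <- gsea(rk, sets, n_perm = 200, seed = 4)
  b <- gsea(rk, sets, n_perm = 200, seed = 4)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- gsea(rk, sets, n_perm = 200, seed = 5)
  expect_false(identical(a$nes, c$nes))
  expect_true(all(a$p_perm >= 1 / (1 + 200)))
  expect_true(all(a$p_adj >= a$p_perm))
  expect_true(all(sign(a$nes) == sign(a$es), na.rm = TRUE))
  expect_error(gsea(rk, list(big = sprintf("x%04d", 1:400))), "larger")
})

test_that("a planted top-of-ranking set passes; random sets almost never do", {
  withr::local_seed(41)
  n <- 2000
  stats <- sort(rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("g%04d", seq_len(n))
  spike <- names(stats)[1:30]
  sets <- c(list(SPIKE = spike),
            synthetic_gene_sets(names(stats), n_sets = 10,
                                size_range = c(20, 60), seed = 42))
  res <- gsea(stats, sets, n_perm = 500, seed = 43)
  spike_row <- dplyr::filter(res, set_name == "SPIKE")
  expect_true(spike_row$passes)
  expect_gt(spike_row$nes, 1.5)
  expect_false(any(dplyr::filter(res, set_name != "SPIKE")$passes))
})
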