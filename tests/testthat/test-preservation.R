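profiles_from_fc <- function(fc_by_type_tp) {
  # build a minimal fc_profiles-shaped tibble from named log2fc vectors;
  # names are "Type@timepoint"
  purrr::imap_dfr(fc_by_type_tp, function(fc, key) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    tibble::tibble(
      cell_type = parts[1], timepoint = parts[2],
      n_target_cells = 50L, gene_id = names(fc),
      mean_target = 1, mean_baseline = 1, log2fc = unname(fc),
      p_raw = 0.5, p_adj = 0.5, significant = TRUE)
  })
}

test_that("literal day-14 copies reproduce every day-0 profile exactly", {
  exp <- copy_day0_as_day14(tiny_experiment(seed = 26))
  profiles <- suppressMessages(build_profiles(exp, min_cells = 10))
  wide <- tidyr::pivot_wider(
    profiles[, c("cell_type", "timepoint", "gene_id", "log2fc")],
    names_from = "timepoint", values_from = "log2fc")
  expect_equal(wide$day14, wide$day0, tolerance = 1e-14)

  pres <- preservation(profiles)
  d <- preservation_diagonal(pres)
  expect_equal(unname(d), rep(1, length(d)), tolerance = 1e-12)
  # strict row dominance
  for (t in rownames(pres$r)) {
    expect_true(all(pres$r[t, colnames(pres$r) != t] < pres$r[t, t]))
  }
})

test_that("the day-14 baseline excludes the type's own day-0 counterpart", {
  exp <- tiny_experiment(seed = 27)
  cells <- exp$cells
  counts <- cbind(exp$counts_day0, exp$counts_day14)
  profiles <- suppressMessages(build_profiles(exp, min_cells = 10))

  d0 <- dplyr::filter(cells, timepoint == "day0")
  for (type in unique(profiles$cell_type)) {
    n_base_expected <- sum(d0$true_label != type)
    tgt <- dplyr::filter(cells, timepoint == "day14", true_label == type)
    base <- dplyr::filter(d0, true_label != type)
    de <- run_de(counts, tgt$cell_id, base$cell_id,
                 genes = unique(profiles$gene_id))
    got <- dplyr::filter(profiles, cell_type == type, timepoint == "day14")
    expect_equal(got$log2fc, de$log2fc)
    expect_equal(nrow(base), n_base_expected)
  }
})

test_that("types below min_cells are skipped; asymmetric availability is handled", {
  exp <- tiny_experiment(seed = 28)
  cells <- exp$cells
  # remove all day-14 microglia: day-0 profile only for that type
  cells <- dplyr::filter(cells,
    !(timepoint == "day14" & true_label == "Microglia"))
  counts <- cbind(exp$counts_day0, exp$counts_day14)
  profiles <- suppressMessages(
    build_profiles(counts, cells, min_cells = 10))
  mic <- dplyr::filter(profiles, cell_type == "Microglia")
  expect_setequal(unique(mic$timepoint), "day0")

  pres <- preservation(profiles)
  expect_false("Microglia" %in% rownames(pres$r))
  expect_true("Microglia" %in% colnames(pres$r))
  expect_error(suppressMessages(build_profiles(counts, cells, min_cells = 1e6)),
               "min_cells")
})

test_that("the gene universe is the sorted union of significant genes", {
  profs <- profiles_from_fc(list(
    "A@day0" = c(gb = 1, ga = 2),
    "B@day0" = c(gb = 0.5, gc = -1)))
  profs$significant <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(compile_gene_universe(profs), c("ga", "gb"))

  profs$significant <- rep(FALSE, 4)
  expect_error(compile_gene_universe(profs), "significant")

  withr::local_seed(29)
  profs$significant <- runif(4) > 0.5 | c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(compile_gene_universe(profs),
               sort(unique(profs$gene_id[profs$significant])))
})

test_that("day-14-only significant genes enter the universe only when asked", {
  profs <- profiles_from_fc(list(
    "A@day0" = c(g1 = 1, g2 = 2, g3 = 0),
    "A@day14" = c(g1 = 1, g2 = 2, g3 = 3)))
  profs$significant <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(compile_gene_universe(profs, include_day14 = TRUE),
               c("g1", "g3"))
  expect_equal(compile_gene_universe(profs, include_day14 = FALSE), "g1")
})

test_that("preservation entries match the direct Pearson formula", {
  profs <- profiles_from_fc(list(
    "A@day0" = c(g1 = 1, g2 = 2, g3 = 3),
    "B@day0" = c(g1 = 1, g2 = 0, g3 = -1),
    "A@day14" = c(g1 = 1, g2 = 2, g3 = 4),
    "B@day14" = c(g1 = 2, g2 = 0, g3 = -2)))
  pres <- preservation(profs, universe = c("g1", "g2", "g3"))
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(pres$r["A", "A"], pearson(c(1, 2, 4), c(1, 2, 3)))
  expect_equal(round(pres$r["A", "A"], 4), 0.9820)
  expect_equal(pres$r["B", "B"], 1)       # (2,0,-2) vs (1,0,-1)
  expect_equal(pres$r["B", "A"], pearson(c(2, 0, -2), c(1, 2, 3)))
})

test_that("constant profiles give NA entries, and small universes error", {
  profs <- profiles_from_fc(list(
    "A@day0" = c(g1 = 1, g2 = 1, g3 = 1),
    "A@day14" = c(g1 = 0, g2 = 1, g3 = 2)))
  pres <- preservation(profs, universe = c("g1", "g2", "g3"))
  expect_true(is.na(pres$r["A", "A"]))
  expect_error(preservation(profs, universe = c("g1", "g2")), "at least 3")
  expect_error(preservation(profs, universe = c("g1", "g2", "gX")), "absent")
})

test_that("a gene that is significant nowhere does not affect the matrix", {
  exp <- tiny_experiment(seed = 30)
  profiles <- suppressMessages(build_profiles(exp, min_cells = 10))
  never <- setdiff(unique(profiles$gene_id),
                   profiles$gene_id[profiles$significant])
  expect_gt(length(never), 0)
  pruned <- dplyr::filter(profiles, gene_id != never[1])
  a <- preservation(profiles)
  b <- preservation(pruned)
  expect_identical(a$universe, b$universe)
  expect_equal(a$r, b$r)
})

test_that("composition counts and fractions are exact and normalized", {
  cells <- tibble::tibble(
    sample_id = "s1",
    timepoint = rep("day0", 10),
    label = c(rep("A", 4), rep("B", 6)))
  comp <- composition(cells)
  expect_equal(comp$fraction[comp$cell_type == "A"], 0.4)
  expect_equal(sum(comp$fraction), 1)

  exp <- tiny_experiment(seed = 31)
  comp2 <- composition(exp$cells, label_col = "true_label")
  sums <- comp2 |>
    dplyr::group_by(sample_id, timepoint) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # deterministic allocation makes configured day-14 fractions exact
  neuron14 <- dplyr::filter(comp2, timepoint == "day14",
                            cell_type == "Neuron")
  expect_equal(neuron14$n, round(0.20 * 240))
  expect_lt(abs(neuron14$fraction - 0.20), 0.05)
})

test_that("drift_sweep returns one row per (delta, seed) with sane correlations", {
  sweep <- suppressMessages(drift_sweep(
    deltas = c(0, 1), seeds = 1:2,
    config = sim_config(n_genes = 300, n_cells_day0 = 240,
                        n_cells_day14 = 240, n_markers_per_type = 10),
    min_cells = 10))
  expect_equal(nrow(sweep), 4)
  expect_true(all(abs(sweep$mean_diag_r) <= 1))
  agg <- tapply(sweep$mean_diag_r, sweep$delta, mean)
  expect_gt(agg[["0"]], agg[["1"]])
})

test_that("tidy, glance and autoplot work on a preservation matrix", {
  exp <- copy_day0_as_day14(tiny_experiment(seed = 32))
  pres <- preservation(suppressMessages(build_profiles(exp, min_cells = 10)))
  td <- tidy(pres)
  expect_setequal(names(td), c("day14_type", "day0_type", "r", "n_genes_used"))
  expect_equal(nrow(td), length(pres$r))
  gl <- glance(pres)
  expect_equal(gl$mean_diag_r, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(pres), "ggplot")
})
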