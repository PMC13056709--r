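# Preranked permutation GSEA. Genes are ranked by their day-14 vs day-0
# log2 fold change within a cell type; each gene set gets the classic
# weighted Kolmogorov-Smirnov enrichment score, a gene-label permutation
# null preserving set size, sign-stratified NES normalization, and a BH
# correction across sets.

#' Day-14 vs day-0 differential expression within one cell type
#'
#' [run_de()] with the type's day-14 cells as target and its own day-0
#' cells as baseline — the within-type temporal contrast that feeds the
#' enrichment analysis.
#'
#' @param x A `sim_experiment` or gene-by-cell count matrix.
#' @param cells Per-cell tibble (`cell_id`, `timepoint`, label column);
#'   defaults to the experiment's table.
#' @param cell_type Type to contrast.
#' @param label_col Label column (default `"label"`, falling back to
#'   `"true_label"`).
#' @param min_cells Minimum cells required at each timepoint (default 20).
#' @param config A [de_config()].
#' @return A [run_de()] tibble.
#' @export
temporal_de <- function(x, cells = NULL, cell_type, label_col = "label",
                        min_cells = 20, config = de_config()) {
  if (inherits(x, "sim_experiment")) {
    counts <- cbind(x$counts_day0, x$counts_day14)
    cells <- cells %||% x$cells
  } else {
    counts <- x
    if (is.null(cells)) abort("`cells` is required when `x` is a matrix.")
  }
  cells <- as_tibble(cells)
  if (!label_col %in% names(cells) && "true_label" %in% names(cells)) {
    label_col <- "true_label"
  }
  sub <- dplyr::filter(cells, .data[[label_col]] %in% cell_type)
  ids <- split(sub$cell_id, sub$timepoint)
  for (tp in c("day0", "day14")) {
    if (length(ids[[tp]] %||% character(0)) < min_cells) {
      abort(sprintf("Type '%s' has %d cells at %s (need >= %d).",
                    cell_type, length(ids[[tp]]), tp, min_cells))
    }
  }
  run_de(counts, ids[["day14"]], ids[["day0"]], config = config)
}

#' Ranking statistic for preranked GSEA
#'
#' Orders genes by decreasing log2 fold change, ties broken
#' lexicographically by gene id.
#'
#' @param de A [run_de()] tibble (needs `gene_id` and `log2fc`).
#' @return Tibble `gene_id`, `stat` in ranking order.
#' @export
rank_statistic <- function(de) {
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc") %in% names(de)))
  if (!nrow(de)) abort("Empty differential-expression table.")
  ord <- order(-de$log2fc, de$gene_id, method = "radix")
  tibble(gene_id = de$gene_id[ord], stat = de$log2fc[ord])
}

as_ranked <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene_id", "stat") %in% names(ranked)))
    setNames(ranked$stat, ranked$gene_id)
  } else {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)))
    ranked
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at a gene in the set the running sum rises by
#' `|stat|^p / sum of |stat|^p over the set's genes`, elsewhere it falls by
#' `1 / (N - N_hits)`. The enrichment score is the running sum's signed
#' extremum (the deviation of largest magnitude; a positive-negative tie
#' resolves positive).
#'
#' @param ranked Output of [rank_statistic()] or a named numeric vector in
#'   ranking order.
#' @param gene_set Character vector of gene ids; must intersect the ranked
#'   genes and not cover them all.
#' @param p Weighting exponent (default 1; 0 gives the unweighted KS form).
#' @return List with `es` and `running`, a tibble (`position`, `gene_id`,
#'   `in_set`, `running_sum`).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  stats_ <- as_ranked(ranked)
  N <- length(stats_)
  hit <- names(stats_) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) abort("The gene set does not intersect the ranked genes.")
  if (nh == N) abort("The gene set covers every ranked gene.")
  w <- abs(stats_)^p
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / nh, N)
  step <- ifelse(hit, inc, -1 / (N - nh))
  running <- cumsum(step)
  i <- which.max(abs(running))
  es_hi <- max(running)
  es_lo <- min(running)
  es <- if (es_hi >= -es_lo) es_hi else es_lo
  list(
    es = es,
    running = tibble(position = seq_len(N), gene_id = names(stats_),
                     in_set = hit, running_sum = running)
  )
}

# ES from sorted hit positions only — O(set size), used for permutations.
# `wp` is |stat|^p over the whole ranked list.
es_from_positions <- function(pos, wp, N) {
  nh <- length(pos)
  nm <- N - nh
  denom <- sum(wp[pos])
  w <- if (denom > 0) wp[pos] / denom else rep(1 / nh, nh)
  tops <- cumsum(w) - (pos - seq_len(nh)) / nm
  bottoms <- tops - w
  hi <- max(tops, if (pos[1] > 1) -1 / nm else -Inf)
  lo <- min(bottoms)
  if (hi >= -lo) hi else lo
}

#' Preranked GSEA with a gene-permutation null
#'
#' For each gene set: the enrichment score on the observed ranking; a null
#' of `n_perm` enrichment scores from random same-size gene subsets (gene
#' label permutation); `nes = es / mean(|null es| of the same sign)`;
#' `p_perm = (1 + k) / (1 + m)` where `m` counts same-sign null scores and
#' `k` those at least as extreme; BH across sets. A set passes when
#' `|nes| > nes_min` and `p_adj < alpha`.
#'
#' @param ranked Output of [rank_statistic()] or a named numeric vector.
#' @param collection Named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm Permutations per set (>= 100).
#' @param seed Integer seed; results are a pure function of the inputs.
#' @param nes_min Threshold on `|nes|` (default 1.5).
#' @param alpha Threshold on the BH-adjusted permutation p (default 0.05).
#' @param p Weighting exponent passed to the enrichment score.
#' @return A `gsea_result` tibble: `set_name`, `size`, `es`, `nes`,
#'   `p_perm`, `p_adj`, `passes`.
#' @export
gsea <- function(ranked, collection, n_perm = 1000, seed = 1,
                 nes_min = 1.5, alpha = 0.05, p = 1) {
  stats_ <- as_ranked(ranked)
  N <- length(stats_)
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  stopifnot(is.list(collection), !is.null(names(collection)))
  too_big <- lengths(collection) > N
  if (any(too_big)) {
    abort(sprintf("Gene set '%s' is larger than the ranked list.",
                  names(collection)[too_big][1]))
  }
  wp <- abs(stats_)^p
  withr::local_seed(seed)

  rows <- purrr::imap(collection, function(set, name) {
    hit_idx <- which(names(stats_) %in% set)
    m <- length(hit_idx)
    if (m == 0 || m == N) {
      inform(sprintf("Skipping set '%s': no usable overlap with the ranking.",
                     name))
      return(NULL)
    }
    es <- es_from_positions(hit_idx, wp, N)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort.int(sample.int(N, m)), wp, N)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    k <- sum(abs(same) >= abs(es))
    p_perm <- (1 + k) / (1 + length(same))
    tibble(set_name = name, size = m, es = es, nes = nes, p_perm = p_perm)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) abort("No gene set overlapped the ranked list.")
  out$p_adj <- bh_adjust(out$p_perm)
  out$passes <- !is.na(out$nes) & abs(out$nes) > nes_min & out$p_adj < alpha
  class(out) <- c("gsea_result", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "nes_min") <- nes_min
  attr(out, "alpha") <- alpha
  out
}

#' Synthetic Hallmark-like gene-set collection
#'
#' Draws named random gene sets from a gene id pool — a stand-in for a
#' curated pathway collection, used in tests and demos.
#'
#' @param genes Gene id pool.
#' @param n_sets Number of sets (default 50).
#' @param size_range Inclusive range of set sizes.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors (`SYNSET_01`, ...).
#' @export
synthetic_gene_sets <- function(genes, n_sets = 50, size_range = c(15, 100),
                                seed = 1) {
  stopifnot(length(genes) >= max(size_range))
  withr::local_seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(m) sample(genes, m))
  setNames(sets, sprintf("SYNSET_%02d", seq_len(n_sets)))
}

#' @rdname gsea
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_passing = sum(x$passes),
    n_perm = attr(x, "n_perm"),
    nes_min = attr(x, "nes_min"),
    alpha = attr(x, "alpha")
  )
}
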