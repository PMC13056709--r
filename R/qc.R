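# Per-cell quality control: gene complexity, library size, mitochondrial
# read share, and per-sample upper outlier caps by the 1.5 x IQR rule.

#' Quality-control thresholds
#'
#' Defaults follow common snRNA-seq practice for cortical tissue: at least
#' 600 detected genes and 1000 UMIs per cell, mitochondrial share strictly
#' below 8%, and per-sample upper caps at Q3 + 1.5 * IQR on gene complexity
#' and library size. Minimum thresholds are inclusive; the mitochondrial
#' rule is exclusive.
#'
#' @param min_genes Minimum detected genes per cell (inclusive).
#' @param min_umis Minimum UMIs per cell (inclusive).
#' @param max_pct_mito Upper bound on the mitochondrial percentage
#'   (exclusive).
#' @param iqr_mult Multiplier for the upper outlier caps.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 600, min_umis = 1000,
                          max_pct_mito = 8, iqr_mult = 1.5) {
  assert_scalar_number(min_genes, "min_genes", 0)
  assert_scalar_number(min_umis, "min_umis", 0)
  assert_scalar_number(max_pct_mito, "max_pct_mito", 0)
  assert_scalar_number(iqr_mult, "iqr_mult", 0, strict = TRUE)
  structure(list(min_genes = min_genes, min_umis = min_umis,
                 max_pct_mito = max_pct_mito, iqr_mult = iqr_mult),
            class = "qc_thresholds")
}

#' Compute per-cell QC metrics
#'
#' For every cell: `n_genes` (genes with count > 0), `n_umis` (column sum)
#' and `pct_mito` (100 * mitochondrial counts / total counts, 0 for
#' all-zero cells).
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Optional per-cell metadata tibble with a `cell_id` column
#'   (e.g. sample and timepoint); joined onto the metrics.
#' @param mito_genes Gene ids to treat as mitochondrial. Defaults to ids
#'   starting with `mito_prefix`. Ids absent from the matrix produce a
#'   warning.
#' @param mito_prefix Prefix used when `mito_genes` is not given.
#' @return A tibble with one row per cell: `cell_id`, any joined metadata,
#'   `n_genes`, `n_umis`, `pct_mito`.
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(n_genes = 100, n_cells_day0 = 30,
#'   n_cells_day14 = 30, n_markers_per_type = 4, seed = 1))
#' compute_cell_metrics(exp$counts_day0, exp$cells)
compute_cell_metrics <- function(counts, cells = NULL, mito_genes = NULL,
                                 mito_prefix = "MT-") {
  counts <- validate_counts(counts)
  if (is.null(mito_genes)) {
    mito_genes <- grep(paste0("^", mito_prefix), rownames(counts),
                       value = TRUE)
  } else {
    missing <- setdiff(mito_genes, rownames(counts))
    if (length(missing)) {
      warn(sprintf("%d mitochondrial gene id(s) not in the matrix: %s",
                   length(missing),
                   paste(head(missing, 5), collapse = ", ")))
      mito_genes <- intersect(mito_genes, rownames(counts))
    }
  }
  n_umis <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  out <- tibble(
    cell_id = colnames(counts),
    n_genes = as.integer(n_genes),
    n_umis = as.integer(n_umis),
    pct_mito = ifelse(n_umis > 0, 100 * mito / n_umis, 0)
  )
  if (!is.null(cells)) {
    cells <- as_tibble(cells)
    stopifnot("cell_id" %in% names(cells))
    out <- dplyr::left_join(
      out, cells[, setdiff(names(cells), c("n_genes", "n_umis", "pct_mito"))],
      by = "cell_id")
    out <- dplyr::relocate(out, "n_genes", "n_umis", "pct_mito",
                           .after = dplyr::last_col())
  }
  out
}

#' Flag cells passing quality control
#'
#' A cell is kept when it meets the minimum gene-complexity and library-size
#' thresholds (inclusive), has a mitochondrial percentage strictly below the
#' cap, and does not exceed the per-sample upper outlier caps
#' `Q3 + iqr_mult * (Q3 - Q1)` on `n_genes` and `n_umis`. Caps are computed
#' within each (sample, timepoint) group on the pre-filter values, with
#' linear-interpolation quartiles.
#'
#' @param cell_table Tibble from [compute_cell_metrics()]; must have
#'   `sample_id` (and optionally `timepoint`) for the per-sample caps.
#' @param thresholds A [qc_thresholds()].
#' @return The input tibble with logical columns `pass_min_genes`,
#'   `pass_min_umis`, `pass_mito`, `pass_gene_cap`, `pass_umi_cap` and their
#'   conjunction `keep`.
#' @export
apply_qc <- function(cell_table, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  cell_table <- as_tibble(cell_table)
  need <- c("cell_id", "n_genes", "n_umis", "pct_mito")
  if (!all(need %in% names(cell_table))) {
    abort("`cell_table` must carry cell_id, n_genes, n_umis, pct_mito.")
  }
  if (nrow(cell_table) == 0) abort("`cell_table` has no cells.")
  grouping <- intersect(c("sample_id", "timepoint"), names(cell_table))
  if (!length(grouping)) {
    abort("`cell_table` needs a `sample_id` column for per-sample caps.")
  }
  cap <- function(x, mult) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] + mult * (q[2] - q[1])
  }
  cell_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(
      pass_min_genes = .data$n_genes >= thresholds$min_genes,
      pass_min_umis = .data$n_umis >= thresholds$min_umis,
      pass_mito = .data$pct_mito < thresholds$max_pct_mito,
      pass_gene_cap = .data$n_genes <= cap(.data$n_genes, thresholds$iqr_mult),
      pass_umi_cap = .data$n_umis <= cap(.data$n_umis, thresholds$iqr_mult),
      keep = .data$pass_min_genes & .data$pass_min_umis & .data$pass_mito &
        .data$pass_gene_cap & .data$pass_umi_cap
    ) |>
    dplyr::ungroup()
}
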