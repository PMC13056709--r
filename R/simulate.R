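# Synthetic paired-timepoint snRNA-seq generator.
#
# The generator emulates the design of a slice-culture fidelity study: a
# day-0 sample with K discrete cell types carrying marker-gene structure,
# and a paired day-14 sample whose per-type expression programs are
# drift-perturbed copies of the day-0 programs, with a timepoint-dependent
# composition shift (neuron depletion by default). Counts are negative
# binomial with per-cell lognormal depth factors; a small gene subset is
# flagged mitochondrial by the "MT-" id prefix.

#' Configuration for a synthetic paired-timepoint experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' defaults describe a desk-scale cortical-tissue-like experiment: four broad
#' cell types with 50 markers each, negative-binomial counts
#' (variance \eqn{\mu + \phi \mu^2}), lognormal library sizes, and a day-14
#' composition shift that depletes neurons.
#'
#' @param n_genes Number of genes.
#' @param n_cells_day0,n_cells_day14 Cells per timepoint.
#' @param cell_types Data frame with columns `name`, `day0_fraction`,
#'   `day14_fraction`. Fractions must each sum to 1.
#' @param n_markers_per_type Marker genes per type; marker sets are disjoint.
#' @param marker_fold Multiplicative expression elevation of a type's markers
#'   in that type (> 1).
#' @param base_mean Expected counts per gene per cell before gene-level
#'   heterogeneity.
#' @param gene_sigma SD of the lognormal per-gene deviation around
#'   `base_mean` (0 = all genes share one baseline).
#' @param dispersion Negative-binomial dispersion \eqn{\phi} (0 = Poisson).
#' @param libsize_sigma Lognormal SD of the per-cell depth factor.
#' @param mito_fraction Fraction of genes flagged mitochondrial ("MT-" ids).
#' @param mito_mean_fold Mean inflation of mitochondrial genes, so the
#'   mitochondrial read share is realistic and the QC rule exercisable.
#' @param drift_sd SD \eqn{\delta} of the independent Gaussian perturbation
#'   added to each (gene, type) log-mean at day 14. 0 means the day-14
#'   expression programs equal the day-0 programs exactly.
#' @param allocation `"deterministic"` (largest-remainder rounding of the
#'   configured fractions, exact composition) or `"multinomial"`.
#' @param seed Integer seed; the experiment is a pure function of the config.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_cells_day0 = 60, n_cells_day14 = 60,
#'                   n_markers_per_type = 5, seed = 1)
#' cfg$cell_types
sim_config <- function(n_genes = 2000,
                       n_cells_day0 = 3000,
                       n_cells_day14 = 3000,
                       cell_types = default_cell_types(),
                       n_markers_per_type = 50,
                       marker_fold = 8,
                       base_mean = 0.5,
                       gene_sigma = 1,
                       dispersion = 0.5,
                       libsize_sigma = 0.4,
                       mito_fraction = 0.01,
                       mito_mean_fold = 5,
                       drift_sd = 0,
                       allocation = c("deterministic", "multinomial"),
                       seed = 1L) {
  allocation <- match.arg(allocation)
  cell_types <- as_tibble(cell_types)
  need <- c("name", "day0_fraction", "day14_fraction")
  if (!all(need %in% names(cell_types))) {
    abort("`cell_types` needs columns name, day0_fraction, day14_fraction.")
  }
  if (anyDuplicated(cell_types$name)) abort("Cell type names must be unique.")
  for (col in c("day0_fraction", "day14_fraction")) {
    f <- cell_types[[col]]
    if (any(f < 0 | f > 1)) abort(sprintf("`%s` must lie in [0, 1].", col))
    if (abs(sum(f) - 1) > 1e-9) {
      abort(sprintf("`%s` must sum to 1 (got %.12f).", col, sum(f)))
    }
  }
  assert_scalar_number(n_genes, "n_genes", 1)
  assert_scalar_number(n_cells_day0, "n_cells_day0", 1)
  assert_scalar_number(n_cells_day14, "n_cells_day14", 1)
  assert_scalar_number(n_markers_per_type, "n_markers_per_type", 0)
  assert_scalar_number(marker_fold, "marker_fold", 1, strict = TRUE)
  assert_scalar_number(base_mean, "base_mean", 0, strict = TRUE)
  assert_scalar_number(gene_sigma, "gene_sigma", 0)
  assert_scalar_number(dispersion, "dispersion", 0)
  assert_scalar_number(libsize_sigma, "libsize_sigma", 0)
  assert_scalar_number(drift_sd, "drift_sd", 0)
  assert_scalar_number(mito_mean_fold, "mito_mean_fold", 0, strict = TRUE)
  if (mito_fraction < 0 || mito_fraction >= 1) {
    abort("`mito_fraction` must lie in [0, 1).")
  }
  if (n_markers_per_type * nrow(cell_types) > n_genes) {
    abort("Marker sets exceed the gene count: need n_markers_per_type * K <= n_genes.")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_cells_day0 = as.integer(n_cells_day0),
      n_cells_day14 = as.integer(n_cells_day14),
      cell_types = cell_types,
      n_markers_per_type = as.integer(n_markers_per_type),
      marker_fold = marker_fold,
      base_mean = base_mean,
      gene_sigma = gene_sigma,
      dispersion = dispersion,
      libsize_sigma = libsize_sigma,
      mito_fraction = mito_fraction,
      mito_mean_fold = mito_mean_fold,
      drift_sd = drift_sd,
      allocation = allocation,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default cell-type composition
#'
#' Four broad types; the day-14 fractions encode the neuron depletion seen
#' in cultured tissue while glia hold or gain share.
#'
#' @return A tibble with columns `name`, `day0_fraction`, `day14_fraction`.
#' @export
default_cell_types <- function() {
  tibble(
    name = c("Neuron", "Astrocyte", "Oligodendrocyte", "Microglia"),
    day0_fraction = c(0.40, 0.20, 0.25, 0.15),
    day14_fraction = c(0.20, 0.30, 0.30, 0.20)
  )
}

#' Largest-remainder allocation of n items to fractions
#' @noRd
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genes, %d + %d cells, %d types, marker_fold %.3g, drift_sd %.3g, seed %d\n",
    x$n_genes, x$n_cells_day0, x$n_cells_day14, nrow(x$cell_types),
    x$marker_fold, x$drift_sd, x$seed
  ))
  invisible(x)
}

#' Simulate a paired day-0 / day-14 experiment
#'
#' Draws two UMI count matrices with known cell-type structure. Per-type
#' expression programs are log-mean vectors; a type's markers get
#' `log(marker_fold)` added in that type only. Day-14 programs are the day-0
#' programs plus independent `N(0, drift_sd^2)` perturbations per
#' (gene, type). Counts for cell `c` of type `k` are negative binomial with
#' mean `L_c * exp(M[g, k])` where `L_c` is the cell's lognormal depth
#' factor, and variance `mu + dispersion * mu^2`.
#'
#' The day-0 matrix depends only on the seed and the day-0 settings — not on
#' `drift_sd` — so drift sweeps share their day-0 data at a fixed seed.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample name used to namespace cell ids
#'   (`sample:timepoint:barcode`).
#' @return A `sim_experiment` list:
#' \describe{
#'   \item{counts_day0, counts_day14}{Sparse gene-by-cell count matrices.}
#'   \item{cells}{Tibble: `cell_id`, `barcode`, `sample_id`, `timepoint`,
#'     `true_label`.}
#'   \item{truth}{Generating parameters: `type_log_means`, `day14_log_means`,
#'     `marker_assignment` (named gene-to-type vector, `NA` for
#'     non-markers), `mito_genes`, the per-cell true labels, and the per-cell
#'     depth factors.}
#' }
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(n_genes = 100, n_cells_day0 = 40,
#'   n_cells_day14 = 40, n_markers_per_type = 4, seed = 7))
#' dim(exp$counts_day0)
#' dplyr::count(exp$cells, timepoint, true_label)
simulate_experiment <- function(config, sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  K <- nrow(config$cell_types)
  types <- config$cell_types$name
  G <- config$n_genes

  n_mito <- floor(config$mito_fraction * G)
  gene_ids <- c(
    if (n_mito > 0) sprintf("MT-%d", seq_len(n_mito)),
    sprintf("GENE%05d", seq_len(G - n_mito))
  )
  mito_genes <- gene_ids[seq_len(n_mito)]

  # per-gene baseline with lognormal heterogeneity; mito genes inflated
  gene_log_mean <- log(config$base_mean) +
    rnorm(G, 0, config$gene_sigma)
  if (n_mito > 0) {
    gene_log_mean[seq_len(n_mito)] <- gene_log_mean[seq_len(n_mito)] +
      log(config$mito_mean_fold)
  }

  # disjoint marker blocks drawn from the non-mito genes
  marker_assignment <- setNames(rep(NA_character_, G), gene_ids)
  nm <- config$n_markers_per_type
  if (nm * K > G - n_mito) {
    abort("Not enough non-mitochondrial genes to host disjoint marker sets.")
  }
  marker_pool <- sample(setdiff(seq_len(G), seq_len(n_mito)), nm * K)
  type_log_means <- matrix(gene_log_mean, nrow = G, ncol = K,
                           dimnames = list(gene_ids, types))
  for (k in seq_len(K)) {
    idx <- marker_pool[((k - 1) * nm + 1):(k * nm)]
    if (nm > 0) {
      marker_assignment[idx] <- types[k]
      type_log_means[idx, k] <- type_log_means[idx, k] + log(config$marker_fold)
    }
  }

  labels_day0 <- allocate_labels(config, "day0_fraction", config$n_cells_day0)
  lib_day0 <- rlnorm(config$n_cells_day0, 0, config$libsize_sigma)
  counts_day0 <- draw_counts(type_log_means, labels_day0, lib_day0,
                             config$dispersion)

  # drift applied after all day-0 draws: day-0 data do not depend on drift_sd
  day14_log_means <- type_log_means +
    matrix(rnorm(G * K, 0, config$drift_sd), G, K)
  labels_day14 <- allocate_labels(config, "day14_fraction", config$n_cells_day14)
  lib_day14 <- rlnorm(config$n_cells_day14, 0, config$libsize_sigma)
  counts_day14 <- draw_counts(day14_log_means, labels_day14, lib_day14,
                              config$dispersion)

  bc0 <- sprintf("d0-%05d", seq_along(labels_day0))
  bc14 <- sprintf("d14-%05d", seq_along(labels_day14))
  colnames(counts_day0) <- paste(sample_id, "day0", bc0, sep = ":")
  colnames(counts_day14) <- paste(sample_id, "day14", bc14, sep = ":")

  cells <- tibble(
    cell_id = c(colnames(counts_day0), colnames(counts_day14)),
    barcode = c(bc0, bc14),
    sample_id = sample_id,
    timepoint = rep(c("day0", "day14"),
                    c(length(labels_day0), length(labels_day14))),
    true_label = c(labels_day0, labels_day14)
  )

  structure(
    list(
      counts_day0 = counts_day0,
      counts_day14 = counts_day14,
      cells = cells,
      truth = list(
        type_log_means = type_log_means,
        day14_log_means = day14_log_means,
        marker_assignment = marker_assignment,
        mito_genes = mito_genes,
        cell_labels_day0 = setNames(labels_day0, colnames(counts_day0)),
        cell_labels_day14 = setNames(labels_day14, colnames(counts_day14)),
        depth_day0 = lib_day0,
        depth_day14 = lib_day14
      ),
      config = config
    ),
    class = "sim_experiment"
  )
}

allocate_labels <- function(config, column, n_cells) {
  fr <- config$cell_types[[column]]
  types <- config$cell_types$name
  counts <- if (config$allocation == "deterministic") {
    largest_remainder(fr, n_cells)
  } else {
    as.integer(stats::rmultinom(1, n_cells, fr))
  }
  empty <- fr > 0 & counts == 0
  if (any(empty)) {
    warn(sprintf(
      "Type(s) %s requested a nonzero %s but received 0 cells (n_cells too small).",
      paste(types[empty], collapse = ", "), column
    ))
  }
  rep(types, counts)
}

draw_counts <- function(log_means, labels, depth, dispersion) {
  G <- nrow(log_means)
  mu <- exp(log_means[, labels, drop = FALSE]) *
    rep(depth, each = G)
  n <- length(mu)
  x <- if (dispersion > 0) {
    rnbinom(n, size = 1 / dispersion, mu = mu)
  } else {
    rpois(n, mu)
  }
  m <- matrix(x, nrow = G, dimnames = list(rownames(log_means), NULL))
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d genes; day0 %d cells, day14 %d cells; %d types; drift_sd %.3g\n",
    nrow(x$counts_day0), ncol(x$counts_day0), ncol(x$counts_day14),
    nrow(x$config$cell_types), x$config$drift_sd
  ))
  invisible(x)
}

#' Replace the day-14 sample by literal copies of the day-0 cells
#'
#' Returns the experiment with `counts_day14` set to a renamed copy of
#' `counts_day0` (and metadata updated to match). Under this substitution
#' every cell type's day-14 fold-change profile is identical to its day-0
#' profile, so the preservation matrix diagonal must equal 1 — the
#' end-to-end identity check for the pipeline.
#'
#' @param experiment A `sim_experiment`.
#' @return The modified `sim_experiment`.
#' @export
copy_day0_as_day14 <- function(experiment) {
  stopifnot(inherits(experiment, "sim_experiment"))
  cp <- experiment$counts_day0
  bc <- sprintf("d14c-%05d", seq_len(ncol(cp)))
  sample_id <- experiment$cells$sample_id[[1]]
  colnames(cp) <- paste(sample_id, "day14", bc, sep = ":")
  experiment$counts_day14 <- cp
  lab0 <- unname(experiment$truth$cell_labels_day0)
  experiment$truth$cell_labels_day14 <- setNames(lab0, colnames(cp))
  experiment$truth$depth_day14 <- experiment$truth$depth_day0
  day0 <- dplyr::filter(experiment$cells, .data$timepoint == "day0")
  experiment$cells <- dplyr::bind_rows(
    day0,
    tibble(cell_id = colnames(cp), barcode = bc, sample_id = sample_id,
           timepoint = "day14", true_label = lab0)
  )
  experiment
}

#' Write a simulated experiment to disk in 10x-style layout
#'
#' Creates `day0/` and `day14/` Matrix-Market triplets (via [write_10x()]),
#' a `cells.csv` metadata table and a `truth.json` with the generating
#' parameters.
#'
#' @param experiment A `sim_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x(experiment$counts_day0, file.path(dir, "day0"))
  write_10x(experiment$counts_day14, file.path(dir, "day14"))
  readr::write_csv(experiment$cells, file.path(dir, "cells.csv"))
  truth <- experiment$truth
  jsonlite::write_json(
    list(
      config = unclass(experiment$config)[setdiff(
        names(experiment$config), "cell_types")],
      cell_types = experiment$config$cell_types,
      marker_assignment = as.list(
        truth$marker_assignment[!is.na(truth$marker_assignment)]),
      mito_genes = truth$mito_genes,
      type_log_means = apply(truth$type_log_means, 2, identity,
                             simplify = FALSE),
      day14_log_means = apply(truth$day14_log_means, 2, identity,
                              simplify = FALSE)
    ),
    file.path(dir, "truth.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
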