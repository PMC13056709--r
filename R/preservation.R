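# The preservation statistic. Each cell type's identity is summarized by
# its log2 fold-change profile against the rest of the day-0 cells; the
# day-14 run substitutes the type's day-14 cells in place of its day-0
# counterpart against that same day-0 baseline. The Pearson correlation of
# the two profiles over a fixed significant-gene universe measures how well
# the type's distinctive expression program survived time in culture.

#' Build day-0 and substituted day-14 fold-change profiles
#'
#' For every cell type with at least `min_cells` cells at day 0, runs
#' [run_de()] with that type's day-0 cells against all other day-0 cells.
#' For every type with at least `min_cells` cells at day 14, repeats the
#' comparison with the day-14 cells substituted in as the target — by
#' default the type's day-0 counterpart is removed from the baseline
#' (`day14_baseline = "substitute"`); `"include"` keeps it, for sensitivity
#' analysis. Types below the floor are skipped with a message, mirroring
#' types that drop out of a sample.
#'
#' The expression floor is applied once, dataset-wide (mean raw count over
#' all cells in `cells`), so every profile is computed over the same gene
#' set.
#'
#' @param x A `sim_experiment`, or a gene-by-cell count matrix covering the
#'   cells in `cells`.
#' @param cells Per-cell tibble with `cell_id`, `timepoint`
#'   (`"day0"`/`"day14"`) and a label column. Defaults to the experiment's
#'   own table when `x` is a `sim_experiment`.
#' @param label_col Name of the label column (default `"label"`, falling
#'   back to `"true_label"` if absent).
#' @param samples Optional sample ids to pool (cells of other samples are
#'   dropped before any DE) — aggregation is raw-cell concatenation.
#' @param min_cells Minimum cells per (type, timepoint) (default 20).
#' @param config A [de_config()].
#' @param day14_baseline `"substitute"` (default) or `"include"`.
#' @param timepoints Which profile rounds to compute (baselines are always
#'   day-0 cells). Computing only `"day14"` lets a caller reuse cached
#'   day-0 profiles when sweeping a day-14 parameter.
#' @param genes Optional fixed gene set overriding the dataset-wide
#'   expression floor (e.g. to hold the tested genes constant across
#'   related experiments).
#' @return An `fc_profiles` tibble: `cell_type`, `timepoint`, `gene_id`,
#'   `mean_target`, `mean_baseline`, `log2fc`, `p_raw`, `p_adj`,
#'   `significant`, `n_target_cells`.
#' @export
build_profiles <- function(x, cells = NULL, label_col = "label",
                           samples = NULL, min_cells = 20,
                           config = de_config(),
                           day14_baseline = c("substitute", "include"),
                           timepoints = c("day0", "day14"),
                           genes = NULL) {
  day14_baseline <- match.arg(day14_baseline)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  if (inherits(x, "sim_experiment")) {
    counts <- cbind(x$counts_day0, x$counts_day14)
    cells <- cells %||% x$cells
  } else {
    counts <- x
    if (is.null(cells)) abort("`cells` is required when `x` is a matrix.")
  }
  counts <- validate_counts(counts)
  cells <- as_tibble(cells)
  if (!label_col %in% names(cells) && "true_label" %in% names(cells)) {
    label_col <- "true_label"
  }
  need <- c("cell_id", "timepoint", label_col)
  if (!all(need %in% names(cells))) {
    abort(sprintf("`cells` must carry columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (!is.null(samples)) {
    cells <- dplyr::filter(cells, .data$sample_id %in% samples)
  }
  cells <- dplyr::filter(cells, !is.na(.data[[label_col]]))
  if (!all(cells$timepoint %in% c("day0", "day14"))) {
    abort("`timepoint` must be 'day0' or 'day14'.")
  }
  if (!any(cells$timepoint == "day0")) abort("No day-0 cells.")

  # one dataset-wide expression floor so all profiles share a gene set
  if (is.null(genes)) {
    keep <- filter_low_expression(counts[, cells$cell_id, drop = FALSE],
                                  config$min_mean_count)
    genes <- names(keep)[keep]
  }
  if (!length(genes)) abort("No genes pass the expression floor.")

  by_tp <- split(cells, cells$timepoint)
  d0 <- by_tp[["day0"]]
  d14 <- by_tp[["day14"]]
  d0_by_type <- split(d0$cell_id, d0[[label_col]])
  type_counts0 <- lengths(d0_by_type)

  one_profile <- function(type, timepoint, target) {
    baseline <- if (timepoint == "day0" || day14_baseline == "substitute") {
      unlist(d0_by_type[setdiff(names(d0_by_type), type)], use.names = FALSE)
    } else {
      d0$cell_id
    }
    if (!length(baseline)) {
      inform(sprintf("Skipping %s@%s: empty day-0 baseline.", type, timepoint))
      return(NULL)
    }
    de <- run_de(counts, target, baseline, config = config, genes = genes)
    dplyr::mutate(de, cell_type = type, timepoint = timepoint,
                  n_target_cells = length(target), .before = 1)
  }

  rows <- list()
  if ("day0" %in% timepoints) {
    for (type in names(d0_by_type)) {
      if (type_counts0[[type]] < min_cells) {
        inform(sprintf("Skipping %s@day0: %d cells < min_cells = %d.",
                       type, type_counts0[[type]], min_cells))
        next
      }
      rows[[paste0(type, "@day0")]] <- one_profile(type, "day0",
                                                   d0_by_type[[type]])
    }
  }
  if (!is.null(d14) && "day14" %in% timepoints) {
    d14_by_type <- split(d14$cell_id, d14[[label_col]])
    for (type in names(d14_by_type)) {
      n <- length(d14_by_type[[type]])
      if (n < min_cells) {
        inform(sprintf("Skipping %s@day14: %d cells < min_cells = %d.",
                       type, n, min_cells))
        next
      }
      rows[[paste0(type, "@day14")]] <- one_profile(type, "day14",
                                                    d14_by_type[[type]])
    }
  }
  if (!length(rows)) abort("No cell type met `min_cells` at any timepoint.")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fc_profiles", class(out))
  attr(out, "de_config") <- config
  attr(out, "min_cells") <- min_cells
  out
}

#' Compile the significant-gene universe
#'
#' The union of genes flagged significant in at least one profile (day-0
#' profiles always; day-14 substituted profiles when
#' `include_day14 = TRUE`, the default), sorted lexicographically.
#'
#' @param profiles An `fc_profiles` tibble.
#' @param include_day14 Include genes significant only in day-14 runs.
#' @return Ordered character vector of gene ids; an empty union is an
#'   error.
#' @export
compile_gene_universe <- function(profiles, include_day14 = TRUE) {
  stopifnot(is.data.frame(profiles))
  use <- profiles$significant &
    (include_day14 | profiles$timepoint == "day0")
  universe <- sort(unique(profiles$gene_id[use]), method = "radix")
  if (!length(universe)) {
    abort("No gene is significant in any included profile.")
  }
  universe
}

#' Cross-timepoint preservation matrix
#'
#' Pearson correlation between every day-14 profile's log2 fold changes and
#' every day-0 profile's, restricted to the gene universe — all universe
#' genes enter regardless of per-profile significance. A constant profile
#' yields an undefined (`NA`) entry, never 0.
#'
#' @param profiles An `fc_profiles` tibble containing both timepoints.
#' @param universe Gene universe; defaults to
#'   [compile_gene_universe()] of `profiles`. At least 3 genes; every
#'   universe gene must be present in every profile.
#' @return A `preservation_matrix`: list with `r` (day-14 types in rows,
#'   day-0 types in columns), `n_genes_used`, and `universe`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
preservation <- function(profiles, universe = NULL) {
  stopifnot(is.data.frame(profiles))
  universe <- universe %||% compile_gene_universe(profiles)
  if (length(universe) < 3) {
    abort("The gene universe must contain at least 3 genes.")
  }
  mat_for <- function(tp) {
    sub <- dplyr::filter(profiles, .data$timepoint == tp)
    if (!nrow(sub)) abort(sprintf("No %s profiles.", tp))
    wide <- tidyr::pivot_wider(
      sub[, c("gene_id", "cell_type", "log2fc")],
      names_from = "cell_type", values_from = "log2fc")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$gene_id
    missing <- setdiff(universe, rownames(m))
    if (length(missing)) {
      abort(sprintf("%d universe gene(s) absent from the %s profiles (e.g. %s).",
                    length(missing), tp, missing[1]))
    }
    if (anyNA(m)) abort(sprintf("Missing log2fc entries in the %s profiles.", tp))
    m[universe, , drop = FALSE]
  }
  m0 <- mat_for("day0")
  m14 <- mat_for("day14")
  r <- suppressWarnings(cor(m14, m0, method = "pearson"))
  structure(
    list(r = r, n_genes_used = length(universe), universe = universe),
    class = "preservation_matrix"
  )
}

#' @export
print.preservation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<preservation_matrix> %d day-14 x %d day-0 types over %d genes\n",
              nrow(x$r), ncol(x$r), x$n_genes_used))
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname preservation
#' @param x A `preservation_matrix`.
#' @param ... Unused.
#' @method tidy preservation_matrix
#' @export
tidy.preservation_matrix <- function(x, ...) {
  as_tibble(x$r, rownames = "day14_type") |>
    tidyr::pivot_longer(-"day14_type", names_to = "day0_type",
                        values_to = "r") |>
    dplyr::mutate(n_genes_used = x$n_genes_used)
}

#' @rdname preservation
#' @method glance preservation_matrix
#' @export
glance.preservation_matrix <- function(x, ...) {
  shared <- intersect(rownames(x$r), colnames(x$r))
  diag_r <- x$r[cbind(shared, shared)]
  tibble(
    n_day14_types = nrow(x$r),
    n_day0_types = ncol(x$r),
    n_genes_used = x$n_genes_used,
    mean_diag_r = mean(diag_r),
    min_diag_r = if (length(diag_r)) min(diag_r) else NA_real_
  )
}

#' Diagonal of a preservation matrix
#'
#' Per-type self correlation (day-14 vs day-0 of the same type), for the
#' types present at both timepoints.
#'
#' @param x A `preservation_matrix`.
#' @return Named numeric vector.
#' @export
preservation_diagonal <- function(x) {
  stopifnot(inherits(x, "preservation_matrix"))
  shared <- intersect(rownames(x$r), colnames(x$r))
  setNames(x$r[cbind(shared, shared)], shared)
}

#' Drift-recovery sweep
#'
#' Parameter-recovery analysis for the preservation statistic: simulates
#' paired experiments over a grid of drift values and replicate seeds,
#' builds day-0 and substituted day-14 profiles with the generator's true
#' labels, and records the mean diagonal preservation correlation. Because
#' the day-0 data do not depend on the drift parameter, day-0 profiles are
#' computed once per seed over a fixed day-0-derived gene set and reused
#' across the grid.
#'
#' @param deltas Drift standard deviations to sweep.
#' @param seeds Replicate seeds.
#' @param config Base [sim_config()]; its `drift_sd` and `seed` are
#'   overridden by the grid.
#' @param min_cells Per-(type, timepoint) cell floor.
#' @param de A [de_config()].
#' @return Tibble: `delta`, `seed`, `mean_diag_r`, `min_diag_r`,
#'   `n_genes_used`.
#' @export
drift_sweep <- function(deltas = c(0, 0.2, 0.5, 1),
                        seeds = 1:5,
                        config = sim_config(),
                        min_cells = 20,
                        de = de_config()) {
  rows <- list()
  for (seed in seeds) {
    day0_profiles <- NULL
    genes <- NULL
    for (delta in deltas) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      cfg$drift_sd <- delta
      experiment <- simulate_experiment(cfg)
      if (is.null(day0_profiles)) {
        # gene floor fixed on day-0 cells so every run shares one gene set
        d0 <- dplyr::filter(experiment$cells, .data$timepoint == "day0")
        keep <- filter_low_expression(
          experiment$counts_day0[, d0$cell_id, drop = FALSE],
          de$min_mean_count)
        genes <- names(keep)[keep]
        day0_profiles <- build_profiles(
          experiment, min_cells = min_cells, config = de,
          timepoints = "day0", genes = genes)
      }
      day14_profiles <- build_profiles(
        experiment, min_cells = min_cells, config = de,
        timepoints = "day14", genes = genes)
      profiles <- dplyr::bind_rows(day0_profiles, day14_profiles)
      pres <- preservation(profiles, compile_gene_universe(profiles))
      diag_r <- preservation_diagonal(pres)
      rows[[length(rows) + 1]] <- tibble(
        delta = delta, seed = seed,
        mean_diag_r = mean(diag_r), min_diag_r = min(diag_r),
        n_genes_used = pres$n_genes_used)
    }
  }
  dplyr::bind_rows(rows)
}

#' Cell-type composition table
#'
#' Cell counts and within-group fractions per (group, timepoint,
#' cell type) — the numbers behind the stacked composition bar charts.
#'
#' @param cells Per-cell tibble with `timepoint` and a label column.
#' @param group_by Grouping column (default `"sample_id"`); use `NULL` for
#'   a single aggregate.
#' @param label_col Label column (default `"label"`, falling back to
#'   `"true_label"`).
#' @return Tibble: group, `timepoint`, `cell_type`, `n`, `fraction`
#'   (fractions sum to 1 within each group-timepoint).
#' @export
composition <- function(cells, group_by = "sample_id", label_col = "label") {
  cells <- as_tibble(cells)
  if (!label_col %in% names(cells) && "true_label" %in% names(cells)) {
    label_col <- "true_label"
  }
  stopifnot(all(c("timepoint", label_col) %in% names(cells)))
  cells <- dplyr::filter(cells, !is.na(.data[[label_col]]))
  keys <- c(group_by, "timepoint")
  cells |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, label_col)))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::rename(cell_type = dplyr::all_of(label_col))
}
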