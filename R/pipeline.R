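# End-to-end orchestration: simulate or read counts, QC, annotate, build
# fold-change profiles, compile the gene universe, preservation matrix,
# composition table, within-type temporal DE and GSEA — each stage writing
# a CSV, with a manifest of file hashes so a rerun is verifiably identical.

#' Assemble and validate a pipeline configuration
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param simulate A [sim_config()] to generate the input experiment, or
#'   `NULL` to read counts from disk.
#' @param counts_dirs Named list with `day0` and `day14` 10x-style
#'   directories (used when `simulate` is `NULL`).
#' @param cells_csv Per-cell metadata CSV (`cell_id`, `sample_id`,
#'   `timepoint`, optional `label`); required when reading from disk.
#' @param qc A [qc_thresholds()].
#' @param mito_prefix Gene-id prefix marking mitochondrial genes.
#' @param annotate `"truth"` (simulated experiments only: reference built
#'   from the generator's expected profiles), `"provided"` (use the label
#'   column of the cells table), or a list with `fine_expr_csv` (gene x
#'   fine-label matrix, first column gene id) and `mapping_csv`
#'   (columns `fine`, `broad`).
#' @param marker_top_n Markers per class pair for annotation.
#' @param de A [de_config()].
#' @param min_cells Per-(type, timepoint) cell floor for profiles and
#'   temporal DE.
#' @param include_day14 Include day-14-only significant genes in the
#'   universe.
#' @param day14_baseline Baseline mode for the substituted day-14 runs.
#' @param samples Optional sample ids to pool before any DE.
#' @param gmt Optional GMT path; when given, temporal DE + GSEA run for
#'   every type meeting `min_cells` at both timepoints.
#' @param n_perm,nes_min,gsea_alpha GSEA settings.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            simulate = sim_config(seed = seed),
                            counts_dirs = NULL,
                            cells_csv = NULL,
                            qc = qc_thresholds(),
                            mito_prefix = "MT-",
                            annotate = "truth",
                            marker_top_n = 50,
                            de = de_config(),
                            min_cells = 20,
                            include_day14 = TRUE,
                            day14_baseline = "substitute",
                            samples = NULL,
                            gmt = NULL,
                            n_perm = 1000,
                            nes_min = 1.5,
                            gsea_alpha = 0.05) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` is mandatory: every stochastic stage must be seeded.")
  }
  cfg <- list(seed = as.integer(seed), simulate = simulate,
              counts_dirs = counts_dirs, cells_csv = cells_csv, qc = qc,
              mito_prefix = mito_prefix, annotate = annotate,
              marker_top_n = marker_top_n, de = de, min_cells = min_cells,
              include_day14 = include_day14,
              day14_baseline = day14_baseline, samples = samples, gmt = gmt,
              n_perm = n_perm, nes_min = nes_min, gsea_alpha = gsea_alpha)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$qc, "qc_thresholds"), inherits(cfg$de, "de_config"))
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$counts_dirs) || is.null(cfg$cells_csv)) {
      abort("Without `simulate`, both `counts_dirs` and `cells_csv` are required.")
    }
    for (tp in c("day0", "day14")) {
      d <- cfg$counts_dirs[[tp]]
      if (is.null(d) || !dir.exists(d)) {
        abort(sprintf("validation: counts directory for %s not found: %s",
                      tp, d %||% "<missing>"))
      }
    }
    if (!file.exists(cfg$cells_csv)) {
      abort(sprintf("validation: cells table not found: %s", cfg$cells_csv))
    }
    if (identical(cfg$annotate, "truth")) {
      abort("annotate = 'truth' requires a simulated experiment.")
    }
  } else {
    stopifnot(inherits(cfg$simulate, "sim_config"))
  }
  if (is.list(cfg$annotate)) {
    for (f in c("fine_expr_csv", "mapping_csv")) {
      if (is.null(cfg$annotate[[f]]) || !file.exists(cfg$annotate[[f]])) {
        abort(sprintf("validation: annotation file `%s` not found.", f))
      }
    }
  } else if (!cfg$annotate %in% c("truth", "provided")) {
    abort("`annotate` must be 'truth', 'provided', or a list of reference paths.")
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt)) {
    abort(sprintf("validation: GMT file not found: %s", cfg$gmt))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `simulate`, `qc` and `de` blocks map onto [sim_config()],
#' [qc_thresholds()] and [de_config()].
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("The config must set `seed`.")
  args <- y
  args$simulate <- if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$cell_types)) {
      sim_args$cell_types <- dplyr::bind_rows(sim_args$cell_types)
    }
    if (is.null(sim_args$seed)) sim_args$seed <- y$seed
    do.call(sim_config, sim_args)
  } else {
    NULL
  }
  args$qc <- do.call(qc_thresholds, y$qc %||% list())
  args$de <- do.call(de_config, y$de %||% list())
  do.call(pipeline_config, args)
}

#' Simulate an experiment and write it to disk
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The `sim_experiment`, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  experiment <- simulate_experiment(config)
  write_experiment(experiment, dir)
  invisible(experiment)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full preservation pipeline
#'
#' Executes, in order: simulate/read, QC, annotation, fold-change profiles,
#' gene universe, preservation matrix, composition, and (when a gene-set
#' collection is configured) temporal DE + GSEA per cell type. Every stage
#' writes a CSV under `out_dir`, and `manifest.json` records the seed and
#' an MD5 per output so reruns can be verified byte-identical.
#'
#' @param config A `pipeline_config` or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`cells`,
#'   `profiles`, `universe`, `preservation`, `composition`, `gsea`) and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  # ---- input
  experiment <- NULL
  if (!is.null(config$simulate)) {
    experiment <- stage("simulate", simulate_experiment(config$simulate))
    counts <- cbind(experiment$counts_day0, experiment$counts_day14)
    cells <- experiment$cells
  } else {
    counts <- stage("read", {
      d0 <- read_10x(config$counts_dirs$day0)
      d14 <- read_10x(config$counts_dirs$day14)
      if (!identical(rownames(d0), rownames(d14))) {
        abort("day0 and day14 matrices disagree on gene ids.")
      }
      cbind(d0, d14)
    })
    cells <- stage("read", {
      tb <- readr::read_csv(config$cells_csv, show_col_types = FALSE)
      stopifnot(all(c("cell_id", "sample_id", "timepoint") %in% names(tb)))
      tb
    })
  }

  # ---- qc
  cells_qc <- stage("qc", {
    metrics <- compute_cell_metrics(counts, cells,
                                    mito_prefix = config$mito_prefix)
    apply_qc(metrics, config$qc)
  })
  emit(cells_qc, "cells_qc.csv")
  kept <- dplyr::filter(cells_qc, .data$keep)
  inform(sprintf("qc: kept %d of %d cells.", nrow(kept), nrow(cells_qc)))

  # ---- annotate
  labelled <- stage("annotate", {
    if (identical(config$annotate, "provided")) {
      lab <- intersect(c("label", "true_label"), names(kept))[1]
      if (is.na(lab)) abort("No label column in the cells table.")
      dplyr::mutate(kept, label = .data[[lab]])
    } else {
      reference <- if (identical(config$annotate, "truth")) {
        reference_from_truth(experiment)
      } else {
        fine <- readr::read_csv(config$annotate$fine_expr_csv,
                                show_col_types = FALSE)
        mapping <- readr::read_csv(config$annotate$mapping_csv,
                                   show_col_types = FALSE)
        collapse_reference(fine, mapping)
      }
      norm <- log_normalize(counts[, kept$cell_id, drop = FALSE])
      labels <- assign_labels(norm, reference, config$marker_top_n)
      dplyr::left_join(kept, labels, by = "cell_id")
    }
  })
  emit(labelled, "labels.csv")

  # ---- profiles / universe / preservation / composition
  profiles <- stage("profiles", build_profiles(
    counts, labelled, label_col = "label", samples = config$samples,
    min_cells = config$min_cells, config = config$de,
    day14_baseline = config$day14_baseline))
  emit(profiles, "profiles.csv")

  universe <- stage("universe",
                    compile_gene_universe(profiles, config$include_day14))
  emit(tibble(gene_id = universe), "universe.csv")

  pres <- stage("preservation", preservation(profiles, universe))
  emit(tidy(pres), "preservation_long.csv")
  emit(as_tibble(pres$r, rownames = "day14_type"), "preservation_matrix.csv")

  comp <- stage("composition", composition(labelled))
  emit(comp, "composition.csv")

  # ---- temporal DE + GSEA
  gsea_tab <- NULL
  if (!is.null(config$gmt)) {
    gsea_tab <- stage("gsea", {
      collection <- read_gmt(config$gmt)
      lab_counts <- dplyr::count(labelled, .data$label, .data$timepoint)
      eligible <- lab_counts |>
        dplyr::filter(!is.na(.data$label), .data$n >= config$min_cells) |>
        dplyr::count(.data$label) |>
        dplyr::filter(.data$n == 2) |>
        dplyr::pull(.data$label)
      purrr::map(eligible, function(type) {
        de <- temporal_de(counts, labelled, type, label_col = "label",
                          min_cells = config$min_cells, config = config$de)
        res <- gsea(rank_statistic(de), collection, n_perm = config$n_perm,
                    seed = config$seed, nes_min = config$nes_min,
                    alpha = config$gsea_alpha)
        dplyr::mutate(as_tibble(res), cell_type = type, .before = 1)
      }) |>
        dplyr::bind_rows()
    })
    emit(gsea_tab, "gsea.csv")
  }

  manifest <- list(
    package = "preservatr",
    seed = config$seed,
    stages = c("simulate/read", "qc", "annotate", "profiles", "universe",
               "preservation", "composition",
               if (!is.null(config$gmt)) "gsea"),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cells = labelled, profiles = profiles, universe = universe,
                 preservation = pres, composition = comp, gsea = gsea_tab,
                 manifest = manifest))
}
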