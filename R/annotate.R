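# Reference-based broad-class annotation. A fine-label median expression
# matrix is collapsed to broad classes, the query is log-normalized, and
# each cell is scored against every class by Spearman rank correlation over
# a marker feature space derived from the reference, with one refinement
# round restricted to the top-2 classes' mutual markers. This captures the
# discriminative core of iterative reference classifiers (SingleR and kin)
# in a single deterministic pass; it is deliberately not a numerical
# replication of any of them.

#' Collapse a fine-label reference into broad classes
#'
#' Averages the fine-label median-expression columns within each broad
#' class, yielding a gene-by-broad-class reference matrix.
#'
#' @param fine_expr Gene-by-fine-label matrix (rownames = gene ids) or a
#'   data frame whose first column is `gene_id`.
#' @param mapping Fine-to-broad mapping: a data frame with columns `fine`
#'   and `broad`, or a named character vector (names = fine labels). Every
#'   fine column must be mapped.
#' @return A `reference_profile`: list with `genes`, `classes`, and the
#'   gene-by-class `expr` matrix.
#' @export
#' @examples
#' fine <- matrix(c(1, 3, 3, 5), nrow = 2,
#'                dimnames = list(c("g1", "g2"), c("f1", "f2")))
#' collapse_reference(fine, c(f1 = "B", f2 = "B"))$expr
collapse_reference <- function(fine_expr, mapping) {
  if (is.data.frame(fine_expr)) {
    m <- as.matrix(fine_expr[, -1, drop = FALSE])
    rownames(m) <- fine_expr[[1]]
    fine_expr <- m
  }
  storage.mode(fine_expr) <- "double"
  if (is.null(rownames(fine_expr)) || is.null(colnames(fine_expr))) {
    abort("`fine_expr` needs gene rownames and fine-label colnames.")
  }
  if (any(fine_expr < 0)) abort("Reference expression must be nonnegative.")
  if (is.data.frame(mapping)) {
    stopifnot(all(c("fine", "broad") %in% names(mapping)))
    mapping <- setNames(as.character(mapping$broad), mapping$fine)
  }
  fine <- colnames(fine_expr)
  unmapped <- setdiff(fine, names(mapping))
  if (length(unmapped)) {
    abort(sprintf("Unmapped fine label(s): %s",
                  paste(unmapped, collapse = ", ")))
  }
  broad <- unique(unname(mapping[fine]))
  expr <- vapply(broad, function(b) {
    cols <- fine[mapping[fine] == b]
    rowMeans(fine_expr[, cols, drop = FALSE])
  }, numeric(nrow(fine_expr)))
  expr <- matrix(expr, nrow = nrow(fine_expr),
                 dimnames = list(rownames(fine_expr), broad))
  if (any(colSums(expr) == 0)) {
    abort("Reference has an all-zero broad-class column.")
  }
  new_reference_profile(expr)
}

new_reference_profile <- function(expr) {
  structure(
    list(genes = rownames(expr), classes = colnames(expr), expr = expr),
    class = "reference_profile"
  )
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %d genes x %d classes: %s\n",
              length(x$genes), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Build a broad-class reference from a simulated experiment's truth
#'
#' Uses the generator's per-type day-0 expected expression as the fine-label
#' matrix with an identity fine-to-broad mapping — a ground-truth reference
#' for testing annotation recovery.
#'
#' @param experiment A `sim_experiment`.
#' @return A `reference_profile`.
#' @export
reference_from_truth <- function(experiment) {
  stopifnot(inherits(experiment, "sim_experiment"))
  collapse_reference(
    exp(experiment$truth$type_log_means),
    setNames(colnames(experiment$truth$type_log_means),
             colnames(experiment$truth$type_log_means))
  )
}

#' Log-normalize a count matrix
#'
#' Scales each cell to a common target depth and applies `log(1 + x)`:
#' entry `= log1p(scale * count / depth)`. Zero-depth cells map to all-zero
#' columns.
#'
#' @param counts Gene-by-cell count matrix.
#' @param scale Target depth (default 1e4).
#' @return A sparse gene-by-cell matrix of log-normalized expression.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  counts <- validate_counts(counts)
  assert_scalar_number(scale, "scale", 0, strict = TRUE)
  depth <- Matrix::colSums(counts)
  fac <- ifelse(depth > 0, scale / depth, 0)
  out <- counts %*% Matrix::Diagonal(x = fac)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  methods::as(out, "generalMatrix")
}

# Top-n marker genes for every ordered class pair, by log reference
# difference. Ties resolve by gene order for determinism.
pair_markers <- function(reference, marker_top_n) {
  lr <- log1p(reference$expr)
  cls <- reference$classes
  out <- list()
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (i == j) next
      d <- lr[, i] - lr[, j]
      top <- order(-d, seq_along(d))[seq_len(min(marker_top_n, length(d)))]
      out[[paste(cls[i], cls[j], sep = "|")]] <- reference$genes[top]
    }
  }
  out
}

#' Assign broad-class labels to cells
#'
#' Scores each cell against each reference class by Spearman rank
#' correlation (average ranks on ties) over a marker feature space: the
#' union, over ordered class pairs, of the `marker_top_n` genes with the
#' largest log reference difference. A refinement round then rescores each
#' cell against only its top two classes, over those two classes' mutual
#' markers, and the final label is the winner of that round (ties broken by
#' class order). Cells are labelled independently of one another.
#'
#' @param query Gene-by-cell matrix of log-normalized expression (see
#'   [log_normalize()]).
#' @param reference A `reference_profile`.
#' @param marker_top_n Markers per ordered class pair (default 50).
#' @param min_common Minimum genes shared between query and reference.
#' @return A tibble: `cell_id`, `label`, `score`, `runner_up_label`,
#'   `delta` (score minus runner-up score, nonnegative). Cells with no
#'   expressed feature genes get `NA` label and score.
#' @export
assign_labels <- function(query, reference, marker_top_n = 50,
                          min_common = 20) {
  stopifnot(inherits(reference, "reference_profile"))
  if (length(reference$classes) == 0) abort("Reference has no classes.")
  common <- intersect(rownames(query), reference$genes)
  if (length(common) < min_common) {
    abort(sprintf("Only %d genes shared with the reference (need >= %d).",
                  length(common), min_common))
  }
  ref <- new_reference_profile(reference$expr[common, , drop = FALSE])
  query <- query[common, , drop = FALSE]
  cls <- ref$classes
  K <- length(cls)
  cells <- colnames(query)

  if (K == 1) {
    sc <- spearman_scores(query, ref$expr)
    return(tibble(cell_id = cells, label = cls, score = sc[, 1],
                  runner_up_label = NA_character_, delta = 0))
  }

  markers <- pair_markers(ref, marker_top_n)
  feats <- unique(unlist(markers, use.names = FALSE))
  S <- spearman_scores(query[feats, , drop = FALSE], ref$expr[feats, ])

  # top-2 classes per cell; ties resolve to the earlier class
  ord <- apply(S, 1, function(s) order(-s, seq_along(s))[1:2])
  top1 <- ord[1, ]
  top2 <- ord[2, ]

  label <- rep(NA_character_, length(cells))
  runner <- rep(NA_character_, length(cells))
  score <- rep(NA_real_, length(cells))
  delta <- rep(NA_real_, length(cells))

  pair_key <- paste(pmin(top1, top2), pmax(top1, top2))
  for (key in unique(pair_key)) {
    idx <- which(pair_key == key)
    ab <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    a <- ab[1]; b <- ab[2]
    f <- unique(c(markers[[paste(cls[a], cls[b], sep = "|")]],
                  markers[[paste(cls[b], cls[a], sep = "|")]]))
    S2 <- spearman_scores(query[f, idx, drop = FALSE],
                          ref$expr[f, c(a, b), drop = FALSE])
    pick <- ifelse(is.na(S2[, 1]) | is.na(S2[, 2]), NA_integer_,
                   ifelse(S2[, 2] > S2[, 1], 2L, 1L))
    ok <- !is.na(pick)
    label[idx[ok]] <- cls[c(a, b)][pick[ok]]
    runner[idx[ok]] <- cls[c(a, b)][3L - pick[ok]]
    score[idx[ok]] <- S2[cbind(which(ok), pick[ok])]
    delta[idx[ok]] <- abs(S2[ok, 1] - S2[ok, 2])
  }
  tibble(cell_id = cells, label = label, score = score,
         runner_up_label = runner, delta = delta)
}

# cells x classes Spearman correlation matrix; NA for constant cells
spearman_scores <- function(query, ref_expr) {
  q <- as.matrix(query)
  suppressWarnings(t(cor(ref_expr, q, method = "spearman")))
}
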