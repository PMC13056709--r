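# Two-group differential expression with an exact negative-binomial test.
#
# The test conditions on a gene's pooled total T = sum_A + sum_B. Writing
# n_A, n_B for the groups' effective masses (sums of member size factors)
# and phi for the gene's dispersion, the group sums are NB with means
# n_A * mu, n_B * mu and dispersions phi / n_A, phi / n_B under the null
# mu = T / (n_A + n_B). Both group-sum distributions then share the same NB
# success probability (it depends only on phi * mu), so the conditional
# probability of observing a in group A given T reduces to
#
#   P(a | T)  proportional to  C(a + r_A - 1, a) * C(T - a + r_B - 1, T - a)
#
# with r_A = n_A / phi, r_B = n_B / phi — a negative-hypergeometric-type
# law evaluated by a log-ratio recurrence. The two-sided p-value sums
# P(a | T) over all outcomes no more probable than the observed one
# (minimum-likelihood method). phi = 0 reduces to the conditional binomial
# (Poisson) test.

#' Differential-expression configuration
#'
#' @param alpha Significance level for the BH-adjusted p-value.
#' @param min_mean_count Expression floor: a gene is tested only when its
#'   mean raw count across the cells in the comparison is at least this.
#' @param pseudocount Added to both normalized group means inside the log2
#'   fold change, keeping it finite.
#' @param shrinkage_weight Prior mass `w0` of the dispersion shrinkage
#'   toward the across-gene mean: the shrunk value is
#'   `(1 - w) * phi_hat + w * mean(phi_hat)` with
#'   `w = w0 / (w0 + n_genes_used)`. `NULL` (default) sets `w0` to the
#'   number of genes used, i.e. `w = 1/2`.
#' @return A `de_config` list.
#' @export
de_config <- function(alpha = 0.05, min_mean_count = 1, pseudocount = 1,
                      shrinkage_weight = NULL) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie in (0, 1).")
  }
  assert_scalar_number(min_mean_count, "min_mean_count", 0)
  assert_scalar_number(pseudocount, "pseudocount", 0, strict = TRUE)
  if (!is.null(shrinkage_weight)) {
    assert_scalar_number(shrinkage_weight, "shrinkage_weight", 0)
  }
  structure(list(alpha = alpha, min_mean_count = min_mean_count,
                 pseudocount = pseudocount,
                 shrinkage_weight = shrinkage_weight),
            class = "de_config")
}

#' Median-ratio size factors
#'
#' `factor_c = depth_c / median(depths of cells with nonzero depth)`.
#' Zero-depth cells get `NA` (unusable for normalization).
#'
#' @param counts Gene-by-cell count matrix.
#' @return Named numeric vector of per-cell size factors.
#' @export
size_factors <- function(counts) {
  counts <- validate_counts(counts)
  depth <- Matrix::colSums(counts)
  nz <- depth > 0
  if (!any(nz)) abort("All cells have zero depth; cannot normalize.")
  f <- depth / median(depth[nz])
  f[!nz] <- NA_real_
  setNames(f, colnames(counts))
}

#' Low-expression gene mask
#'
#' A gene is kept when its average raw count across cells is at least
#' `min_mean_count` (genes below the floor are excluded from testing and
#' from the multiple-testing denominator).
#'
#' @param counts Gene-by-cell count matrix.
#' @param min_mean_count Expression floor (default 1).
#' @return Named logical vector over genes.
#' @export
filter_low_expression <- function(counts, min_mean_count = 1) {
  counts <- validate_counts(counts)
  setNames(Matrix::rowSums(counts) / ncol(counts) >= min_mean_count,
           rownames(counts))
}

#' Method-of-moments dispersion with shrinkage
#'
#' Per gene, on size-factor-normalized counts, computes the pooled
#' within-group variance `s2` and overall mean `m`, the moment estimate
#' `phi_hat = max(0, (s2 - m) / m^2)`, and shrinks it toward the
#' across-gene mean `xi`: `phi = (1 - w) * phi_hat + w * xi` with
#' `w = w0 / (w0 + G)`. Cells with unusable (NA) size factors are dropped.
#'
#' @param counts Gene-by-cell count matrix.
#' @param groups Factor or character vector over columns with exactly two
#'   levels, each with at least two usable cells.
#' @param shrinkage_weight Prior mass `w0`; `NULL` means `G` (so `w = 1/2`).
#' @param sf Optional precomputed size factors.
#' @return Named numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, groups, shrinkage_weight = NULL,
                                sf = NULL) {
  counts <- validate_counts(counts)
  groups <- as.factor(as.character(groups))
  stopifnot(length(groups) == ncol(counts))
  if (nlevels(groups) != 2) abort("`groups` must have exactly two levels.")
  sf <- sf %||% size_factors(counts)
  usable <- !is.na(sf)
  counts <- counts[, usable, drop = FALSE]
  groups <- droplevels(groups[usable])
  sf <- sf[usable]
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort("Each group needs at least two cells with nonzero depth.")
  }
  n <- ncol(counts)
  y <- counts %*% Matrix::Diagonal(x = 1 / sf)

  m <- Matrix::rowSums(y) / n
  # pooled within-group variance
  ss <- 0
  for (lev in levels(groups)) {
    yg <- y[, groups == lev, drop = FALSE]
    mg <- Matrix::rowSums(yg) / ncol(yg)
    ss <- ss + Matrix::rowSums(yg^2) - ncol(yg) * mg^2
  }
  s2 <- ss / (n - 2)
  phi_hat <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  G <- length(phi_hat)
  w0 <- shrinkage_weight %||% G
  w <- if (w0 + G > 0) w0 / (w0 + G) else 0
  phi <- pmax(0, (1 - w) * phi_hat + w * mean(phi_hat))
  setNames(phi, rownames(counts))
}

# log unnormalized conditional pmf over a = 0..T (phi > 0 branch)
cond_log_pmf <- function(T, rA, rB) {
  if (T == 0) return(0)
  a <- 0:(T - 1)
  lr <- log(a + rA) + log(T - a) - log(a + 1) - log(T - a - 1 + rB)
  c(0, cumsum(lr))
}

exact_nb_p_one <- function(sum_target, total, mass_target, mass_baseline,
                           dispersion, tie_slack = 1e-12) {
  if (total == 0) return(1)
  if (dispersion <= 0) {
    lh <- dbinom(0:total, total, mass_target / (mass_target + mass_baseline),
                 log = TRUE)
  } else {
    lh <- cond_log_pmf(total, mass_target / dispersion,
                       mass_baseline / dispersion)
  }
  # log-space summation: extreme observations underflow on the raw scale
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  sel <- lh <= lh[sum_target + 1] + log1p(tie_slack)
  p <- exp(lse(lh[sel]) - lse(lh))
  min(1, max(p, .Machine$double.xmin))
}

#' Exact conditional negative-binomial test
#'
#' Two-sided p-value for a difference in a gene's expression between two
#' groups, conditioning on the pooled total count (see the header of this
#' file for the conditional law). Outcomes whose conditional probability is
#' at most the observed one's (with a `1 + 1e-12` slack for floating-point
#' ties) are summed. `total = 0` gives `p = 1` by convention. Vectorized
#' over genes.
#'
#' @param sum_target,sum_baseline Per-gene total raw counts in each group.
#' @param mass_target,mass_baseline Effective group masses (sums of member
#'   size factors), strictly positive.
#' @param dispersion Per-gene NB dispersion (0 = Poisson/binomial case).
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' # Poisson case with equal masses reduces to the exact binomial test:
#' exact_nb_test(8, 2, 1, 1, 0) # 112/1024
exact_nb_test <- function(sum_target, sum_baseline, mass_target,
                          mass_baseline, dispersion) {
  n <- max(length(sum_target), length(sum_baseline), length(dispersion))
  sum_target <- rep_len(sum_target, n)
  sum_baseline <- rep_len(sum_baseline, n)
  mass_target <- rep_len(mass_target, n)
  mass_baseline <- rep_len(mass_baseline, n)
  dispersion <- rep_len(dispersion, n)
  if (any(sum_target < 0 | sum_baseline < 0)) abort("Counts must be >= 0.")
  if (any(mass_target <= 0 | mass_baseline <= 0)) {
    abort("Effective group masses must be > 0.")
  }
  if (any(!is.finite(dispersion)) || any(dispersion < 0)) {
    abort("`dispersion` must be finite and >= 0.")
  }
  vapply(seq_len(n), function(i) {
    exact_nb_p_one(sum_target[i], sum_target[i] + sum_baseline[i],
                   mass_target[i], mass_baseline[i], dispersion[i])
  }, numeric(1))
}

#' Pseudocounted log2 fold change
#'
#' `log2((mean_target + pseudocount) / (mean_baseline + pseudocount))` on
#' size-factor-normalized group means; always finite for a positive
#' pseudocount.
#'
#' @param mean_target,mean_baseline Normalized group means (>= 0).
#' @param pseudocount Stabilizing constant (default 1).
#' @return Numeric vector.
#' @export
log2_fold_change <- function(mean_target, mean_baseline, pseudocount = 1) {
  if (any(mean_target < 0 | mean_baseline < 0)) {
    abort("Group means must be >= 0.")
  }
  log2((mean_target + pseudocount) / (mean_baseline + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, returned in input order. Inputs must
#' lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise >= the input, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Run two-group differential expression
#'
#' For the union of the two cell groups: filters low-expression genes
#' (unless a fixed `genes` vector is supplied), computes median-ratio size
#' factors, estimates shrunk moment dispersions, applies the exact
#' conditional NB test per gene, forms pseudocounted log2 fold changes of
#' the normalized group means, and BH-adjusts across the tested genes.
#'
#' @param counts Gene-by-cell count matrix covering all named cells.
#' @param target_cells,baseline_cells Disjoint, non-empty character vectors
#'   of cell ids.
#' @param config A [de_config()].
#' @param genes Optional fixed gene set to test (bypasses the expression
#'   floor); useful to hold the tested universe constant across related
#'   comparisons.
#' @return A tibble: `gene_id`, `mean_target`, `mean_baseline`, `log2fc`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
run_de <- function(counts, target_cells, baseline_cells,
                   config = de_config(), genes = NULL) {
  stopifnot(inherits(config, "de_config"))
  counts <- validate_counts(counts)
  if (!length(target_cells) || !length(baseline_cells)) {
    abort("Both cell groups must be non-empty.")
  }
  if (length(intersect(target_cells, baseline_cells))) {
    abort("Target and baseline cell sets overlap.")
  }
  missing <- setdiff(c(target_cells, baseline_cells), colnames(counts))
  if (length(missing)) {
    abort(sprintf("%d cell id(s) absent from the count matrix.",
                  length(missing)))
  }
  sub <- counts[, c(target_cells, baseline_cells), drop = FALSE]
  if (is.null(genes)) {
    keep <- filter_low_expression(sub, config$min_mean_count)
    genes <- names(keep)[keep]
  } else {
    missing_g <- setdiff(genes, rownames(sub))
    if (length(missing_g)) {
      abort(sprintf("%d requested gene(s) absent from the matrix.",
                    length(missing_g)))
    }
  }
  if (!length(genes)) abort("No genes left after the expression floor.")

  sf <- size_factors(sub)
  grp <- factor(rep(c("target", "baseline"),
                    c(length(target_cells), length(baseline_cells))),
                levels = c("target", "baseline"))
  usable <- !is.na(sf)
  sub <- sub[genes, usable, drop = FALSE]
  grp <- grp[usable]
  sf <- sf[usable]
  if (sum(grp == "target") < 1 || sum(grp == "baseline") < 1) {
    abort("A group lost all cells to zero depth.")
  }

  phi <- estimate_dispersion(sub, grp, config$shrinkage_weight, sf = sf)
  tgt <- grp == "target"
  sum_t <- Matrix::rowSums(sub[, tgt, drop = FALSE])
  sum_b <- Matrix::rowSums(sub[, !tgt, drop = FALSE])
  mass_t <- sum(sf[tgt])
  mass_b <- sum(sf[!tgt])

  mean_t <- sum_t / mass_t
  mean_b <- sum_b / mass_b
  p_raw <- exact_nb_test(sum_t, sum_b, mass_t, mass_b, phi)
  p_adj <- bh_adjust(p_raw)
  tibble(
    gene_id = genes,
    mean_target = unname(mean_t),
    mean_baseline = unname(mean_b),
    log2fc = log2_fold_change(unname(mean_t), unname(mean_b),
                              config$pseudocount),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    significant = unname(p_adj) < config$alpha
  )
}
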