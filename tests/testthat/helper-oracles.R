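# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Exact conditional NB test by brute force: unnormalized products of
# dnbinom (or dpois) group-sum densities over a = 0..T, minimum-likelihood
# two-sided summation with the same floating-point tie slack.
oracle_exact_nb_p <- function(sum_target, total, mass_target, mass_baseline,
                              dispersion) {
  if (total == 0) return(1)
  a <- 0:total
  mu <- total / (mass_target + mass_baseline)
  if (dispersion <= 0) {
    dens <- stats::dpois(a, mass_target * mu) *
      stats::dpois(total - a, mass_baseline * mu)
  } else {
    dens <- stats::dnbinom(a, mu = mass_target * mu,
                           size = mass_target / dispersion) *
      stats::dnbinom(total - a, mu = mass_baseline * mu,
                     size = mass_baseline / dispersion)
  }
  dens <- dens / sum(dens)
  sum(dens[dens <= dens[sum_target + 1] * (1 + 1e-12)])
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(1, q_sorted)[order(o)]
}

# Weighted KS running sum stepped one gene at a time.
oracle_es <- function(stats_named, gene_set, p = 1) {
  hit <- names(stats_named) %in% gene_set
  denom <- sum(abs(stats_named[hit])^p)
  miss_step <- 1 / (length(stats_named) - sum(hit))
  running <- numeric(length(stats_named))
  cur <- 0
  for (i in seq_along(stats_named)) {
    cur <- if (hit[i]) {
      cur + (if (denom > 0) abs(stats_named[i])^p / denom else 1 / sum(hit))
    } else {
      cur - miss_step
    }
    running[i] <- cur
  }
  hi <- max(running)
  lo <- min(running)
  if (hi >= -lo) hi else lo
}

# Small default experiment for unit tests: fast but structured enough for
# labels and profiles to be recoverable.
tiny_experiment <- function(seed = 1, drift_sd = 0, ...) {
  simulate_experiment(sim_config(
    n_genes = 300, n_cells_day0 = 240, n_cells_day14 = 240,
    n_markers_per_type = 10, drift_sd = drift_sd, seed = seed, ...))
}
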