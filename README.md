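# preservatr

Does a cell type still behave like itself after two weeks in a dish?
`preservatr` answers this for paired single-nucleus RNA-seq designs — a
tissue sample profiled immediately (day 0) and again after time in
organotypic slice culture (day 14) — by scoring how well each cell type's
*transcriptional identity* is preserved.

The core statistic: for each cell type \(t\), build its **identity
profile** at day 0 — the per-gene log2 fold changes of \(t\)'s cells
against all other day-0 cells, tested with an exact conditional
negative-binomial test. Then rebuild the profile with \(t\)'s **day-14
cells substituted in** against the same day-0 baseline. Over the fixed
universe \(U\) of genes significantly variable (BH-adjusted p < 0.05) in
at least one profile, the preservation score is

$$ r[t_{14},\, t_0] \;=\; \mathrm{corr}_{g \in U}\!\left( \mathrm{log_2FC}^{(14)}_{g,t},\; \mathrm{log_2FC}^{(0)}_{g,t} \right) $$

A diagonal entry near 1 means the type's distinctive up/down-regulation
pattern survived culture; off-diagonal structure shows whether a drifted
type now resembles a different day-0 type. Around this statistic the
package provides the full supporting pipeline — per-cell QC (600 genes /
1000 UMIs / <8% mitochondrial / per-sample 1.5×IQR caps), rank-correlation
broad-class annotation, composition tables, within-type day-14 vs day-0
contrasts with preranked permutation GSEA — plus a seeded
negative-binomial generator of paired experiments with known cell-type
structure, expression drift and composition shifts, so every stage is
testable against ground truth.

Everything is tidyverse-native: functions take data frames, return
tibbles, chain with the pipe, and result objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate a paired experiment whose day-14 expression programs drift by
`drift_sd = 0.3` on the log scale, build both rounds of profiles with the
generator's true labels, and correlate:

```r
library(preservatr)

exp <- simulate_experiment(sim_config(drift_sd = 0.3, seed = 1))
profiles <- build_profiles(exp)
pres <- preservation(profiles)
pres
#> <preservation_matrix> 4 day-14 x 4 day-0 types over 657 genes
#>                 Astrocyte Microglia Neuron Oligodendrocyte
#> Astrocyte           0.914     0.003 -0.422          -0.097
#> Microglia           0.021     0.922 -0.370          -0.028
#> Neuron             -0.420    -0.361  0.918          -0.509
#> Oligodendrocyte    -0.100    -0.041 -0.510           0.912

glance(pres)
#> # A tibble: 1 × 5
#>   n_day14_types n_day0_types n_genes_used mean_diag_r min_diag_r
#>           <int>        <int>        <int>       <dbl>      <dbl>
#> 1             4            4          657       0.917       0.912
```

The 657 genes are the compiled significant-gene universe. Each diagonal
entry (~0.91–0.92) says that, after a 0.3-SD perturbation of its
expression program, a type's day-14 fold-change profile still correlates
strongly with its day-0 identity; every row is diagonally dominant, so no
type has drifted into resembling another. With `drift_sd = 0` the diagonal
is ≈ 1; with literal day-0 copies substituted as day 14
(`copy_day0_as_day14()`) it is exactly 1. `autoplot(pres)` draws the
heatmap.

Downstream, the culture-effect contrast and its pathway summary:

```r
de14 <- temporal_de(exp, cell_type = "Microglia")
res <- gsea(rank_statistic(de14),
            synthetic_gene_sets(de14$gene_id, n_sets = 50, seed = 1),
            n_perm = 1000, seed = 1)
```

`run_pipeline(pipeline_config(seed = 1), "out/")` runs every stage in
order (simulate/read → QC → annotate → profiles → universe → preservation
→ composition → GSEA) and writes one CSV per stage plus an MD5 manifest;
reruns with the same config are byte-identical. On-disk inputs use the
10x-style Matrix-Market triplet (`read_10x()`/`write_10x()`) and GMT gene
sets (`read_gmt()`).

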