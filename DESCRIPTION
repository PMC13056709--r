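Package: preservatr
Title: Cell-Type Transcriptional Identity Preservation in Paired
    Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well cell types preserve their transcriptional
    identities between paired timepoints of a single-nucleus RNA-seq
    experiment, as in organotypic slice-culture fidelity studies. Provides
    per-cell quality control (gene complexity, library size, mitochondrial
    fraction, IQR outlier caps), reference-based broad-class annotation by
    rank correlation, exact negative-binomial differential expression with
    moment dispersion estimates and shrinkage, a timepoint-substitution
    design for log2 fold-change profiles, cross-timepoint Pearson
    preservation matrices, cell-type composition tables, and preranked
    permutation gene-set enrichment analysis. A negative-binomial
    synthetic-data generator with known cell-type structure, expression
    drift, and composition shifts makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
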