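Package: hoxmeth
Title: HOX Methylation Signatures, Consensus Clustering and Single-Nucleus
    Cell States in Oligodendroglioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying HOX-locus DNA methylation in
    IDH-mutant, 1p/19q-codeleted oligodendroglioma. Implements a
    three-probe HOXD12 gene-body beta-value signature with a
    midpoint hypermethylation threshold and the probe screening that
    motivates it; stability-filtered consensus clustering of pooled
    pan-HOX gene-body probes over repeated stochastic embeddings with
    a switch-frequency exclusion rule; single-nucleus neoplastic
    calling from inferred arm-level dosage (1p/19q codeletion
    universality), marker-based cell typing, bin-matched program
    scoring with a permutation test and FDR-gated cell-state
    assignment; and the cohort statistics used throughout (log-rank,
    Cox with VIF screening, Fisher, Mann-Whitney, Benjamini-Hochberg,
    dip and Shapiro-Wilk wrappers, and rule-based genomic and
    treatment calls). Ships seeded synthetic-data generators with
    known planted truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    igraph,
    irlba,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    survival,
    sva,
    tibble,
    utils,
    uwot,
    withr
Suggests:
    mclust,
    quadprog,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
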