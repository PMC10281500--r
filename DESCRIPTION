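Package: scTrioITH
Title: Integrative Single-Cell Trio-Omics Analysis of Tumor Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting intratumoral heterogeneity from parallel
    single-cell measurements of somatic copy number, DNA methylation (WCG
    context), chromatin accessibility (GCH context) and RNA expression in the
    same cells. Provides copy-number lineage inference from binned DNA
    coverage, cytosine-context classification and coverage-weighted
    methylation/accessibility quantification at global, repeat-class and
    promoter resolution, stringent rank-sum based differential expression and
    differential promoter methylation calling with per-patient consistency
    filtering, tissue-signature derivation and overlap analysis, PCA-based
    differentiation-state assignment, per-cell rank-based gene-set scoring,
    and cross-omics integration summaries. Includes a synthetic trio-omics
    cohort generator with planted clonal, epigenetic and transcriptomic
    structure used as ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    cluster,
    mclust,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
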