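---
title: "Methods: integrative single-cell trio-omics analysis of tumor heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative single-cell trio-omics analysis of tumor heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

scTrioITH analyzes cohorts in which every single cell is profiled on three
molecular layers at once: binned DNA read coverage (somatic copy-number
alterations, SCNAs), bisulfite cytosine calls split into WCG and GCH
trinucleotide contexts (endogenous DNA methylation and GpC-methyltransferase
chromatin accessibility, respectively), and a UMI expression matrix. The
package covers the downstream analysis only: it starts from per-cell call
tables and count matrices, not from reads. Alignment, bisulfite mapping and
demultiplexing are out of scope, as is any retrieval of controlled-access
human data; all validation runs on the package's own synthetic cohort
generator.

# The cytosine context model

In a GpC-methyltransferase-treated library every cytosine carries one of two
signals, decided by its trinucleotide:

* **WCG** (W = A or T, then C, then G): a CpG not confounded by GpC, so the
  methylated fraction reports endogenous DNA methylation.
* **GCH** (G, then C, then H = A, C or T): a GpC not confounded by CpG, so
  the methylated fraction reports the exogenous enzyme's access to the DNA,
  i.e. chromatin openness.
* **GCG** is simultaneously CpG and GpC and is excluded, as is every other
  trinucleotide.

`classify_cytosine_context()` implements exactly this partition; cytosines on
the minus strand are classified on the reverse complement, and edge positions
without a flank are excluded. The test suite checks the classifier against an
independent brute-force enumerator over random sequence on both strands: the
partition is total (every C gets exactly one label) and mirror-consistent.

# Quantification

A region's level in a cell is the coverage-weighted fraction
`sum(methylated) / sum(total)` over the context sites falling in the region
(`region_levels()`), never a mean of per-site means — at single-cell depth
most sites have 1–5 reads and site means would be dominated by the shallowest
sites. Levels are *missing* (not zero) below `min_sites = 3` covered sites or
`min_reads = 5` total reads. The same machinery serves genome-wide levels
(`global_level()`, with a low-QC flag below a per-cell site count),
repeat-class levels pooled over all regions of a class
(`repeat_class_levels()`), and promoter windows. Promoters are TSS ± 1 kb by
construction of the annotation; the window is a config choice, not a claim
about any particular genome build.

# One rank-sum engine

All two-group comparisons (differential promoters, differential expression,
between-lineage and between-state methylation) go through a single Wilcoxon
rank-sum implementation, `rank_sum_test()`: the Mann–Whitney U from the rank
formula, an exact two-sided p from the null Wilcoxon distribution when both
groups have ≤ 25 tie-free observations, and a tie-corrected normal
approximation with continuity correction otherwise. The exact branch is
verified against full enumeration of all rank splits, and both branches
against `stats::wilcox.test`.

Differential promoter methylation (`call_dmps()`) tests per-cell promoter
levels, adjusts with Benjamini–Hochberg, and calls a promoter at
`q ≤ 0.05` and `|Δ| ≥ 0.2` (group-mean difference). These defaults are
deliberately conservative for fractions in [0, 1]; both are exposed.
Differential expression (`call_degs()`) works on
`log2(1 + 10,000 · count / cell_total)` values with a stringent call rule:
`q ≤ 0.01`, `|log2FC| ≥ 1` (fold change of de-logged group means with
pseudo-count 1), and ≥ 50% of cells expressing the gene in the up-regulated
group. With `per_patient = TRUE` the test runs within each patient and
`shared_features()` keeps genes called with the same direction in ≥ 80% of
patients — recurrence is counted per direction, so a gene up in some patients
and down in others is never merged into one call.

# Lineages, clusters, states

Copy-number profiles (`compute_scna_profiles()`) are within-cell coverage
shares divided by the median share of a diploid normal panel, median-filtered
over `w = 3` adjacent bins; bins unusable in the panel (zero median share or
< 80% of normals covered) are masked, not dropped. Genetic lineages are
average-linkage hierarchical clusters of `1 − ρ` (Spearman) distances, with
the number of lineages chosen by maximal mean silhouette width over
`k = 2…8` when not fixed. Both the linkage and the cut rule are this
package's choices — hierarchical clustering of SCNA profiles is standard in
the field but the linkage is rarely printed — and labels are ordered by
decreasing lineage size for determinism.

Transcriptomic clusters use the top-variance genes, PCA, and Ward clustering
in component space with the same silhouette rule. The differentiation axis
(`differentiation_axis()`) is selected automatically instead of by visual
inspection: PCA is run over normal and cancer cells jointly; the component
with maximal normal-vs-cancer separation (|AUROC − 0.5|; orientation-free) is
set aside; among the remaining components the axis is the one maximizing the
between-group sum of squares of the best two-way split of per-cluster median
coordinates (exhaustive 1-D two-means over the sorted medians). States are
assigned by thresholding cancer-cell coordinates at the midpoint between the
two cluster-median groups. When histopathology labels exist they orient the
axis (better-differentiated high); otherwise the orientation is recorded as
arbitrary, because a principal component's sign carries no meaning.

Per-cell gene-set activity (`gene_set_scores()`) is a rank statistic: genes
are ranked within each cell (average ranks on ties) and the score is
`(mean rank of set genes − mean rank of all genes) / n_genes`, bounded by
±(n − |S|)/(2n). This is a deliberate, documented substitution for kernel
density based gene-set variation scores: downstream use is purely comparative
(which state has higher immune-pathway activity), which a monotone rank
statistic preserves, and it is exactly reproducible. A permutation-
standardized variant (z against random same-size sets) is available.

# Integration

`lineage_methylation()` summarizes global WCG levels per genetic lineage
(median, IQR, pairwise rank-sum tests) and, where a lineage spans both the
primary tumor and lymph-node metastases, computes
`median(PT) − median(LN)`; a lineage is flagged as apparently shifted when
the absolute difference exceeds 0.05 — i.e. a change of more than five
percentage points of methylation, interpreting the ">5%" convention as an
absolute difference of methylation fractions. `lineage_cluster_contingency()`
quantifies the many-to-many relation between lineages and transcriptomic
clusters with a lineage × cluster table, chi-square (no continuity
correction), Cramér's V and per-lineage Shannon entropy of cluster
composition; the field usually describes this relation qualitatively, so the
choice of summaries is ours. `state_methylation_compare()` checks, per
patient and in primary-tumor cells, the ordering poorer-differentiated >
better-differentiated with both below normal epithelium.
`trio_concordance()` joins the three differential results per gene and
classifies each direction triple; one supporting epigenetic arm suffices for
a concordant class, any opposing arm makes the gene discordant, and the
classification is total.

# The synthetic cohort

`simulate_cohort()` generates the default validation conditions: 2 patients
× 3 clones × 50 cancer cells, 30 normal stomach cells per patient, one
30-cell normal colon reference, 1,000 genome bins, 2,000 promoters, 200
repeat regions in 3 classes (L1 / LTR / satellite), 5,000 genes. All draws
are negative-binomial (coverage, UMIs) or binomial (methylated reads), fully
deterministic under one master seed.

Planted structure, chosen once as stylized but realistic values:

* **Clones**: 8 non-overlapping CNV events per clone, lengths 25–50 bins,
  copy numbers in {0, 1, 3, 4}; coverage 50 reads per diploid bin with NB
  dispersion 0.1.
* **Methylation**: per-clone global WCG levels 0.55 / 0.65 / 0.75 against
  0.80 in normal stomach; cancer repeat levels at 0.80 (L1), 0.85 (LTR) and
  0.67 (satellite) of the cell's global level, reproducing the strong
  repeat-element demethylation and its class ordering; 120 hypermethylated
  and 30 hypomethylated promoters at |Δ| = 0.3 (a ~4:1 hyper:hypo ratio);
  a PT-vs-LN offset of 0.06 for the middle lineage of each patient and 0.02
  for the others, so exactly one lineage per patient crosses the 0.05 flag.
  Genome-bin levels are solved per cell so that the coverage-weighted
  expectation over *all* WCG sites equals the planted global level exactly;
  without this the promoter compartment (mean ≈ 0.5) would bias the
  genome-wide estimator off the planted values.
* **Accessibility**: flat background 0.25; promoters with planted
  methylation changes receive an inverse logit-linear accessibility shift
  (strength 1). Only the direction of the coupling is asserted by the
  biology; the functional form is a modeling choice.
* **Expression**: 500 DEGs at |log2FC| = 2 between cancer and normal stomach
  (10% of genes); a 60-gene colon signature (high in normal colon) of which
  25% is aberrantly activated in cancer cells, and an 80-gene stomach
  signature of which 50% is lost in cancer cells — emulating the aberrant
  colon-program gain and stomach-function loss of gastric cancer cells;
  patient-specific 60-gene cluster marker programs wired many-to-many onto
  the clones (clone A → cluster 1, clone B → clusters 1+2, clone C →
  cluster 3); a shared 80-gene poorer-differentiation program and three
  30-gene immune sets more active in better-differentiated cells. Cluster
  markers are patient-specific on purpose: inter-patient transcriptomic
  heterogeneity is a dominant feature of real tumors, and sharing marker
  programs across patients would let cluster-specific components compete
  with the shared differentiation axis in a way real cohorts do not.
* **States and methylation** are coupled through the clone→cluster map
  alone: the poorer-differentiated cluster is fed by the most-methylated
  clone (0.75), so the ordering poorer > better with both below normal
  emerges from lineage structure without a separate knob.

What the generator does **not** emulate: doublets, batch and plate effects,
patient-specific copy-number ploidy shifts, read-level bisulfite errors,
spatial coordinates, and realistic per-cell coverage distributions (real
ones sit behind controlled access). Passing tests therefore demonstrate
correctness of the estimators and callers under their stated noise models,
not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

Ties in ranks are resolved by average rank everywhere. Hierarchical
clustering, PCA and silhouette selection are deterministic given the input;
PCA component signs are fixed so the largest-magnitude loading is positive,
making projections invariant to cell order. Zero-coverage regions yield
missing levels, never zeros; all-zero DNA cells are excluded with a warning;
zero-total expression cells are dropped before normalization; correlation
pairs sharing < 3 usable bins are missing and later imputed by column mean
with a warning. Empty groups and overlapping group definitions are errors,
as are planted effects with conflicting signs on the same gene for
co-occurring cell selectors.

# Problem sizes

The default cohort (sizes above) was chosen so that the complete pipeline —
simulation, all four analysis stages and the recovery report — runs in about
a minute, and the full test suite, including a 20-rerun null calibration of
the differential-promoter caller (2,000 promoters, 50 vs 50 cells), in a few
minutes on one CPU. Unit tests run on a further-scaled-down cohort (12 cells
per clone, 300 bins, 400 promoters, 800 genes) that keeps every planted
structure intact.

# Known limitations

The copy-number module infers relative profiles from DNA coverage only; no
integer segmentation, breakpoint calling or subclonal-fraction estimation is
attempted. The accessibility analysis reuses the promoter-window machinery
(no nucleosome-depleted-region detection). The gene-set score is a rank
statistic, not a kernel-density enrichment score, and should be interpreted
comparatively. Thresholds that real studies leave in supplements (promoter
window, QC cut-offs, DEG stringency) are declared configuration with the
defaults documented here, not inferred values.
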