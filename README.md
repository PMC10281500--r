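# scTrioITH

Integrative analysis of single-cell "trio-omics" cohorts — cells profiled
simultaneously for somatic copy-number alterations (binned DNA coverage),
DNA methylation and chromatin accessibility (bisulfite cytosine calls in WCG
and GCH trinucleotide contexts), and RNA expression (UMI counts). The
package is aimed at tumor intratumoral-heterogeneity studies: it infers
genetic lineages from copy-number profiles, quantifies methylation and
accessibility from global down to promoter resolution, calls stringent
differential genes and promoters, assigns tumor differentiation states
along a principal-component axis, scores per-cell gene-set activity, and
joins the three layers per cell.

## The methods in brief

* **Cytosine contexts.** In GpC-methyltransferase-treated libraries, a
  cytosine in W‑C‑G (W = A/T) reports endogenous CpG methylation, a cytosine
  in G‑C‑H (H = A/C/T) reports chromatin accessibility, and G‑C‑G is
  ambiguous and excluded. Region levels are coverage-weighted fractions
  Σmeth/Σtotal over in-region sites.
* **Genetic lineages.** Per-cell copy-number ratios are within-cell coverage
  shares normalized to a diploid panel's median share and median-filtered;
  cells are grouped by average-linkage clustering of 1 − ρ (Spearman)
  distances with silhouette-selected k.
* **Differential calling.** One shared Wilcoxon rank-sum engine (exact for
  small tie-free samples, tie-corrected normal approximation otherwise) with
  Benjamini–Hochberg adjustment; promoters are called at q ≤ 0.05 and
  |Δ| ≥ 0.2, genes at q ≤ 0.01, |log2FC| ≥ 1 and ≥ 50% expressing cells,
  optionally requiring per-patient recurrence with direction-aware counting.
* **Differentiation states.** PCA over normal plus cancer cells; the
  normal-vs-cancer separating component (max |AUROC − 0.5|) is set aside and
  the state axis is the component that best splits per-cluster median
  coordinates two ways (exhaustive 1-D two-means); states come from
  thresholding at the split midpoint.
* **Gene-set scores.** Per cell, score = (mean rank of set genes − mean rank
  of all genes) / n_genes ∈ ±(n−|S|)/(2n), with an optional
  permutation-standardized variant.
* **Integration.** Lineage-resolved global methylation with a PT-vs-LN shift
  flag (|Δmedian| > 0.05), lineage × transcriptomic-cluster contingency
  (chi-square, Cramér's V, per-lineage entropy), per-patient
  differentiation-state methylation ordering, and promoter trio concordance
  classes (expression × methylation × accessibility).

A synthetic cohort generator (`simulate_cohort()`) plants all of this
structure — clone-specific copy-number events, lineage-specific global
methylation, repeat-class demethylation, promoter DMPs with inversely
coupled accessibility, tissue-signature programs, a many-to-many
clone-to-cluster map and state-coupled immune programs — and records truth
tables, so every stage is validated by parameter recovery. See the methods
vignette (`vignettes/trio-omics-methods.Rmd`) for models, defaults and
limitations.

## Worked example

```r
library(scTrioITH)
res <- run_pipeline(list(seed = 1), out_dir = "demo")
cat(readLines("demo/report.md"), sep = "\n")
```

prints

```
# trio-omics pipeline report

seed: 1
cells: 390 (300 cancer)
patients: P1, P2

## planted-truth recovery

lineage ARI: P1=1.000 P2=1.000
cluster ARI: P1=1.000 P2=1.000
max clone methylation error: 0.0027
DEG sensitivity: 0.912, empirical FDR: 0.000
DMP sensitivity: 1.000, false discoveries: 0
state accuracy: 1.000 (normal/cancer AUROC 1.000)
contingency recovered exactly: P1=TRUE P2=TRUE
colon-signature overlap fraction: 0.233
stomach-signature overlap fraction: 0.500
immune sets higher in better_diff: TRUE
state ordering ok in 2/2 patients
```

Reading this: both patients' genetic lineages and transcriptomic clusters
match the planted truth exactly (adjusted Rand index 1); per-clone global
methylation medians land within 0.003 of the planted 0.55/0.65/0.75 levels;
the stringent DEG caller recovers 91% of planted |log2FC| = 2 genes with no
false calls across the per-patient consistency filter; all 150 planted
differential promoters are found; the differentiation axis classifies every
cancer cell's state correctly; 23.3% of the derived colon signature is
aberrantly up-regulated in cancer cells and 50% of the stomach signature is
lost; and in both patients poorer-differentiated cancer cells are more
methylated than better-differentiated ones while both stay below normal
epithelium. The `demo/` directory holds the underlying TSV tables
(lineages, DMPs, DEGs, states, scores, contingency tables, per-lineage
methylation).

A thin command-line wrapper is provided in `inst/scripts/trio-ith`
(`trio-ith simulate|run --out DIR --seed N`).

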