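---
title: "Methods: cohort-level single-cell, TCR and histology analysis with mcatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level single-cell, TCR and histology analysis with mcatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcatlas)
```

# Scope and model of the data

`mcatlas` implements the computational stages of a cohort study of
microscopic colitis (MC) that profiles colonic mucosa with single-cell
RNA-seq, paired single-cell TCR sequencing, and quantitative histology
(IHC and RNAscope). Three cohorts are compared throughout: MC patients,
symptomatic controls with chronic diarrhea, and unaffected controls; the
two-control design separates disease-specific signals from symptomatic but
non-inflamed tissue.

The pipeline's carrier object is a `SingleCellExperiment` holding a sparse
gene × cell UMI count matrix plus per-cell metadata (`patient`, `cohort`,
`platform`, optional cluster/cell-type labels). Stages are pure functions
over this carrier and small data frames, so each stage is testable in
isolation.

# Stage by stage

## Cell quality control

`filter_cells()` applies the two standard post-droplet-calling filters:
cells with fewer than 200 detected genes or more than 20% mitochondrial UMI
content are removed. Both thresholds are inclusive on the retained side:
exactly 200 genes or exactly 20% mitochondrial content is kept, matching the
strict inequalities "less than 200" and "more than 20%". Mitochondrial
content is computed as a fraction of total UMI counts (not of detected
genes), the convention "content" ordinarily denotes; the gene-name prefix
(`MT-`) is configurable. Droplet calling itself (EmptyDrops, knee point, FDR
0.01) happens upstream and is recorded only as provenance in the QC report.
Manual exclusions — an overloaded library, clusters defined purely by
mitochondrial genes — are a caller-supplied barcode list, not automated
heuristics.

## Compartment assignment

Mucosal biopsies mix immune, epithelial and stromal cells, which are
separated before any fine-grained analysis. `default_cluster()` mirrors the
standard high-dimensional pipeline: library-size normalization to 10,000
counts with `log1p` (`normalize_log()`), the 2,000 most variable genes,
per-gene scaling, 50 principal components, a shared-nearest-neighbor graph
(k = 20, Jaccard weights, pruned below 1/15) and Louvain modularity
optimization at resolution 2. `score_clusters()` then scores every cluster
against three curated marker sets (epithelial: EPCAM, KRT8, KRT18; stromal:
COL1A1, COL1A2, COL6A1, COL6A2, VWF, PLVAP, CDH5, S100B; immune: CD52, CD2,
CD3D, CD3G, CD3E, CD79A, CD79B, CD14, CD16, CD68, CD83, CSF1R, FCER1G). The
score is the mean over the set's matched genes of the cluster-mean
normalized expression, and the cluster is assigned to the arg-max
compartment. Two deliberate choices:

* **CD16** is a legacy name with no matching HGNC symbol in current
  annotations; it is resolved to *FCGR3A* through a logged alias table
  rather than silently dropped.
* **Ties** cannot be meaningfully ordered, so they break deterministically
  by the marker-list order (immune, epithelial, stromal) with a warning;
  real data essentially never ties.

Scoring uses normalized (not raw) expression; whether the original analysis
averaged raw or normalized values from the expression slot is ambiguous, so
the choice is documented here rather than claimed as fidelity.

## Cluster-stability profiling

`stability_profile()` evaluates candidate clustering resolutions by a
bootstrap-like criterion: at each resolution the full data are clustered
once, then 20 times a random 90% subsample (without replacement) is
reclustered with a fresh derived seed and compared to the full-data labels
restricted to the subsample via the adjusted Rand index (ARI,
Hubert–Arabie). `select_resolution()` scans the per-resolution median ARI in
ascending order and returns the largest resolution before the median starts
decreasing. Three choices the procedure leaves open are fixed as follows:

* **Medians**, not means, summarize the 20 ARI values — robust to the
  occasional pathological subsample.
* **Tolerance 0.01** on "started decreasing": raw medians jitter by a few
  thousandths between adjacent resolutions, and an exact-decrease rule would
  make the selection seed-sensitive.
* **Seed derivation**: per-(resolution, iteration) seeds are derived from
  the master seed with fixed multipliers, so the whole profile is
  reproducible and adding a resolution never changes another resolution's
  subsamples.

`adjusted_rand_index()` accepts barcode-named labelings and compares on the
barcode intersection, which is exactly what the subsample comparison needs.

## Compositional summaries

`per_patient_proportions()` produces the per-patient proportion tables that
underlie cohort boxplots, with the denominator made explicit because the
figures use three different ones: all cells of a compartment
(`all_immune`), all cells of a parent lineage such as all CD8 T cells
(`parent_lineage`), or a restricted class such as cycling cells
(`cycling_only` / `custom`). Patients with an empty denominator get `NA`
proportions and are logged, mirroring the convention that such patients are
simply not plotted. `enrichment_stack()` pools cells per cell type and
scales cohort shares to 100%, retaining per-patient contribution fractions
(the "transparency" breakdown of stacked enrichment columns).
`igg_iga_ratio()` reports the per-patient IgG/IgA plasma-cell ratio from
supplied isotype labels; a patient with no IgA cells is flagged rather than
pseudocounted, since the ratios feed plots, not models. The Bayesian
compositional model used for significance calls in the original analysis
(scCODA) is an external tool; `per_patient_proportions()` emits the count
table it consumes, and its MCMC is deliberately not re-implemented.

## Pseudobulk differential expression

`pb_aggregate()` sums raw counts per (patient, cell type) group in integer
arithmetic and drops groups with fewer than 5 cells. `cohort_de()` compares
cohorts within a cell type on per-patient `log2` counts-per-million
(`cpm_log()`, pseudocount 1) using the Wilcoxon–Mann–Whitney rank-sum test:
exact null when the smaller side has at most 8 patients and there are no
ties, normal approximation with tie correction otherwise. The log2 fold
change is the difference of per-side mean log-CPM, and Benjamini–Hochberg
adjustment is applied per comparison per cell type (matching per-panel
significance reporting; the family definition is otherwise unstated).
The published GLM engines for pseudobulk DE (limma-voom, edgeR) are
external, validated tools; this module's built-in engine is the rank-sum
test on patient-level pseudobulk — assumption-light and verifiable by
enumeration — and `write_pseudobulk()` exports the exact layout the external
engines expect. `cluster_markers()` applies the same test at the single-cell
level for marker discovery, with configurable log-fold-change and
percent-expressed candidate thresholds.

## TCR clonotype analysis

`merge_clonotypes()` reduces a patient's filtered contigs (productive AND
high-confidence only) to clonotypes keyed by the *set* of CDR3 amino-acid
sequences per barcode; identical sets across libraries of one patient merge
into one clonotype with pooled cells and a new patient-scoped ID. From the
merged repertoire: `clonotype_frequencies()` (proportions of
clonotype-bearing cells), `shannon_diversity()` (H = −Σ p log p, natural
log — the default of the ecology package the original analysis cites),
`classify_expanded()` (≥ 2 cells), and `sharing_matrix()` (off-diagonal:
expanded clonotypes with cells in both clusters; diagonal: all unique
clonotypes observed in the cluster — the two conventions the sharing figure
legend defines). `sharing_test()` implements the dual-comparison rule: per
cluster, 2×2 tables of shared vs unique expanded clonotypes (pooled across a
cohort's patients) for MC vs chronic diarrhea and MC vs unaffected, Fisher's
exact test each, BH adjustment across testable clusters within each
comparison, and a flag only when both adjusted p-values fall below 0.05.
Clusters with no expanded clonotypes in one cohort are not testable and are
excluded from that comparison's BH family. Cells without a productive TCR
never enter repertoire denominators.

## Histology count regression

`poisson_fit()` models per-image probe-positive counts as
`count ~ cohort` with MC as the reference level, by maximum likelihood
(IRLS). For RNAscope the log of the image's DAPI-positive cell total enters
as an offset, so coefficients are log rate ratios per cell; for IHC, whose
counts are already normalized per field, the default is no offset (a flag
enables one). In the two-group case the fitted rate ratio equals the
closed-form ratio of pooled rates, which the tests verify exactly.
`quasipoisson_adjust()` estimates over-dispersion as Pearson χ²/df, scales
standard errors by its square root and moves p-values from Wald z to Wald t
on the residual degrees of freedom (the procedure names neither statistic;
these are the conventional choices). `cohort_significance()` applies the two
decision rules: IHC — BH across stains within each comparison, significant
only when both MC-vs-control contrasts pass; RNAscope — raw p < 0.05 in both
contrasts, reported separately for the Poisson and quasi-Poisson fits with
an explicit discordance flag (over-dispersed probes can reach significance
under Poisson alone). `classify_speckle_high()` retains the one pure
threshold from image quantitation: a cell is GZMB-high at ≥ 5 speckles.
Images are treated as independent units; patient-level random effects are a
noted extension, not implemented.

# The synthetic-data generator

Because the study's real data are restricted-access, every stage is
exercised on `sim_config()`-driven synthetic data with known truth:

* **Expression** (`generate_cell_dataset()`): negative-binomial counts
  (size 2) with log-normal gene-level base means, per-cell depth log-normal
  around 2,500 UMIs. Eleven cell types across the three compartments carry
  marker blocks — the compartment's curated markers plus three type-specific
  genes — up-lifted by a factor of 5 (lift 1 produces null data). Thirteen
  `MT-` genes carry a planted per-cell mitochondrial fraction drawn from
  [0.01, 0.10]. Cohort composition defaults plant the disease signal:
  activated CD8 Trm doubled (0.10 vs 0.05) and IgG plasma cells up (0.05 vs
  0.02) in MC.
* **Repertoires** (`generate_repertoire()`): 40 clonotypes per patient,
  half expanded (2 + Poisson(1.5) cells), CDR3s random C…F peptides unique
  by construction, paired TRA with probability 0.8, plus non-productive
  (10%) and low-confidence (5%) decoy contigs to exercise filtering. An
  expanded clonotype spans a second of 6 clusters with probability 0.30 in
  MC vs 0.05 in both control cohorts — the planted sharing excess. Each
  patient's cells split across two libraries so CDR3-set merging is
  exercised.
* **Histology** (`generate_histology()`): DAPI totals Poisson around 500,
  counts Poisson(rate × DAPI) with optional gamma mixing for
  over-dispersion; default probes plant a rate ratio of 2 for GZMB in MC
  (0.04 vs 0.02 per cell) and a null probe (FOXP3), 60 images per cohort.

Cohort sizes default to 8 MC / 6 chronic diarrhea / 5 unaffected patients
and 2,000 cells per patient. One RNG stream per generator is derived from
the master seed with fixed offsets, so calling one generator never perturbs
another and identical `(config, seed)` is byte-identical.

What the generator does **not** emulate: transcriptome-wide co-expression,
doublets, ambient RNA, batch effects between platforms, or V(D)J assembly
noise. Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under its stated model — not that any biological
conclusion transfers to real tissue.

# Problem sizes and calibration checks

The test suite runs everything at desk scale, chosen to finish in minutes
while leaving the statistical checks meaningful:

* Compartment recovery uses 6 patients × 1,000 cells × 400 genes per seed,
  10 seeds; at marker lift 5 assignment recovers ≥ 99% of planted labels.
  Accuracy at this scale is limited by cluster impurity (a handful of
  stray cells per cluster), which shrinks as cell density grows toward the
  study-scale default.
* Null DE calibration uses 2,000 genes with cohort-exchangeable
  composition; the raw rank-sum false-positive rate at p < 0.05 stays
  within ±1.5 points of 5%.
* Sharing inference uses the full default repertoire conditions. Because
  the planted sharing excess is cohort-wide, every cluster carries it;
  detection is scored as the dual rule firing on at least one cluster
  (every firing is a true positive here), with the per-cluster false-flag
  rate under identical sharing verified ≤ 0.05 over 200 null replicates.
  The probability that any single given cluster is flagged — i.e. the
  per-cluster power with roughly one sixth of the expanded clonotypes —
  is around 0.65 at these cohort sizes, which is why detection is defined
  at the repertoire level.
* Poisson interval coverage is verified at 93–97% over 1,000 replicates of
  the default histology configuration, and the planted rate ratio 2 is
  detected by the dual rule under both regressions in ≥ 90% of replicates.

# Numerical conventions and degenerate inputs

* Zero-total cells make the mitochondrial fraction undefined;
  `mito_fraction()` errors, and such cells fall to the gene-count filter in
  `filter_cells()`.
* `fisher_exact_2x2()` returns 1 on any zero margin and clamps the
  two-sided sum at 1 (the underlying enumeration can exceed 1 by round-off).
* A rank-sum comparison where every value is identical is degenerate:
  p = 1 with an explicit flag, and an all-zero gene reports log2FC 0.
* A saturated Poisson fit has Pearson dispersion 0 (after clearing IRLS
  round-off below 1e-12) and is flagged; quasi-Poisson adjustment refuses
  designs with no residual degrees of freedom.
* `select_resolution()` is a pure function of the curve; it never consults
  the RNG.
* Derived seeds stay below 2^31 by modular arithmetic in doubles, so they
  are always valid R integer seeds.

# Known limitations

* The compartment score operates per cluster; a per-cell score is out of
  scope, so compartment errors are bounded below by cluster impurity.
* Pseudobulk DE with 2–8 patients per side has granular exact p-values;
  genome-scale FDR control at these cohort sizes is intrinsically coarse.
* Sharing tests pool clonotypes across patients within a cohort (the
  stratified per-patient variant of the contingency tables is not
  implemented).
* Batch correction (Harmony) and embedding (UMAP) are consumed upstream /
  downstream of this package and are intentionally absent.
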