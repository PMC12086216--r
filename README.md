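# mcatlas

Cohort-level single-cell transcriptomic, TCR-repertoire and histology
analysis for studies of microscopic colitis (MC) — chronic colonic
inflammation diagnosed histologically despite normal-appearing mucosa.
Such studies compare three cohorts (MC, chronic-diarrhea controls,
unaffected controls) across three data modalities, and most of the
analysis is small, well-defined statistics that deserve tested,
reusable implementations:

* **Cell QC** — remove cells with < 200 detected genes or > 20%
  mitochondrial UMI content (both boundaries inclusive on the retained
  side).
* **Compartment assignment** — cluster (PCA → SNN graph → Louvain,
  resolution 2), score each cluster by the mean normalized expression of
  curated immune / epithelial / stromal marker sets, assign by maximum
  score, and split the dataset.
* **Cluster-stability profiling** — at each candidate resolution, recluster
  20 random 90% subsamples and compare to the full-data labels with the
  adjusted Rand index (ARI); select the largest resolution before the
  median ARI starts decreasing.
* **Compositional summaries** — per-patient cell-type proportions under
  explicit denominators, cohort enrichment stacks, and the per-patient
  IgG/IgA plasma-cell ratio.
* **Pseudobulk DE** — sum raw counts per (patient, cell type), drop groups
  with < 5 cells, compare cohorts per gene with the Wilcoxon rank-sum test
  on per-patient log2-CPM, Benjamini–Hochberg adjusted.
* **TCR clonotypes** — merge filtered contigs (productive ∧ high
  confidence) into clonotypes keyed by CDR3 sets, Shannon diversity
  (H = −Σ pᵢ ln pᵢ), expansion (≥ 2 cells), cross-cluster sharing matrices,
  and the dual-cohort test: per cluster, Fisher's exact test on shared vs
  unique expanded clonotypes for MC vs each control, BH-adjusted, flagged
  only when both adjusted p < 0.05.
* **Histology regression** — probe-positive counts per image modeled as
  `count ~ cohort` (MC reference) by Poisson regression with a log DAPI
  offset; quasi-Poisson adjustment via Pearson dispersion
  (SE × √φ, Wald t); dual-comparison significance rules for IHC (BH across
  stains) and RNAscope (raw p, Poisson/quasi-Poisson concordance reported);
  GZMB-high classification at ≥ 5 RNAscope speckles.

The real data for such studies are restricted-access, so the package ships
a **synthetic-data generator** (`sim_config()`, `generate_cell_dataset()`,
`generate_repertoire()`, `generate_histology()`) producing cohort-structured
counts, contig tables and histology counts with planted, recorded ground
truth — marker blocks, composition shifts, clonal expansion/sharing rates,
Poisson rate ratios — against which every stage is tested.

## Worked example

```r
library(mcatlas)

cfg <- sim_config(n_patients = c(MC = 2, chronic_diarrhea = 2, unaffected = 2),
                  n_cells_per_patient = 300, n_genes = 400, seed = 1)
g   <- generate_cell_dataset(cfg)

qc <- filter_cells(g$dataset)
qc$report
#> Cell QC report
#>   cells in:               1800
#>   removed, < 200 genes:   0
#>   removed, > 20% mito:   0
#>   cells out:              1800

norm   <- normalize_log(qc$dataset)
lab    <- default_cluster(qc$dataset, resolution = 2, seed = 1)
scores <- score_clusters(norm, lab)
head(scores$assignment)
#>            1           10           11           12           13           14
#>     "immune"     "immune"     "immune"     "immune"     "immune" "epithelial"

pred <- scores$assignment[as.character(lab$labels)]
mean(pred == g$truth$cells[colnames(qc$dataset), "compartment"])
#> [1] 0.9861111
```

The QC report counts cells against the two filters (none fail here: the
default planted mitochondrial fractions sit well below 20%);
`score_clusters()` assigns each Louvain cluster to the compartment whose
curated markers score highest; at this small problem size the cluster-level
assignment recovers ~98.6% of the planted per-cell compartment labels
(≥ 99% at the denser sizes the test suite uses).

TCR and histology stages work the same way:

```r
reps <- merge_generated_repertoires(generate_repertoire(cfg))
sharing_test(reps)$flags            # dual-Fisher flags per cluster
shannon_diversity(reps[[1]])        # per-patient repertoire diversity

h   <- generate_histology(sim_config(seed = 1))
fit <- quasipoisson_adjust(poisson_fit(h$counts, probe = "GZMB"))
cohort_significance(list(GZMB = fit), mode = "rnascope")$probes
#>   probe testable significant_poisson significant_quasipoisson significant discordant
#> 1  GZMB     TRUE                TRUE                     TRUE        TRUE      FALSE
```

See `vignettes/mcatlas-methods.Rmd` for the full account of the models,
parameter choices and limitations.

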