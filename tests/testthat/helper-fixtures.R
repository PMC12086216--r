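# Fixtures built in code at test time.

suppressPackageStartupMessages({
  library(Matrix)
})

# Minimal SingleCellExperiment from a dense gene x cell matrix.
make_sce <- function(counts, meta = NULL) {
  counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%03d", seq_len(ncol(counts)))
  }
  if (is.null(meta)) {
    meta <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  }
  rownames(meta) <- colnames(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
}

# Desk-scale simulation configuration (2 patients per cohort).
small_config <- function(seed = 1, n_cells = 120, n_genes = 300, ...) {
  sim_config(n_patients = c(MC = 2, chronic_diarrhea = 2, unaffected = 2),
             n_cells_per_patient = n_cells, n_genes = n_genes,
             seed = seed, ...)
}

# Build merged repertoires (with planted cluster labels) from a
# generate_repertoire() result.
merge_generated <- function(rep_out) merge_generated_repertoires(rep_out)

# Hand-built repertoire: clonotype k gets sizes[k] cells spread over
# clusters[[k]] (recycled), enough to exercise sharing logic without the
# generator.
toy_repertoire <- function(patient, cohort, sizes, clusters) {
  stopifnot(length(sizes) == length(clusters))
  rows <- list()
  cluster_map <- character(0)
  cell_idx <- 0L
  for (k in seq_along(sizes)) {
    cdr3 <- sprintf("CTOY%s%02dF", patient, k)
    cl <- rep_len(clusters[[k]], sizes[k])
    for (i in seq_len(sizes[k])) {
      cell_idx <- cell_idx + 1L
      bc <- sprintf("%s_bc%03d", patient, cell_idx)
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = bc, chain = "TRB", cdr3 = cdr3,
        productive = "true", high_confidence = "true",
        stringsAsFactors = FALSE)
      cluster_map[bc] <- cl[i]
    }
  }
  merge_clonotypes(do.call(rbind, rows), patient, cohort, cluster_map)
}
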