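# Internal helpers shared across modules.

# Derive a child RNG seed from a master seed and up to three stream indices.
# Arithmetic in doubles stays below 2^53, result below 2^31, so the value is
# a valid R integer seed. Fixed multipliers keep streams for different
# generators / iterations disjoint: adding one generator call never perturbs
# another's output.
.derive_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  x <- (as.numeric(master) %% 2147483647) * 48271 +
    as.numeric(a) * 7919 + as.numeric(b) * 104729 + as.numeric(c) * 1299709
  as.integer(x %% 2147483629) + 1L
}

.sparse <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    methods::as(m, "CsparseMatrix")
  } else {
    Matrix::Matrix(as.matrix(m), sparse = TRUE)
  }
}

# Extract the counts assay of a CellDataset as a dgCMatrix.
.counts <- function(dataset) {
  stopifnot(methods::is(dataset, "SummarizedExperiment"))
  .sparse(SummarizedExperiment::assay(dataset, "counts"))
}

.cell_meta <- function(dataset) {
  as.data.frame(SummarizedExperiment::colData(dataset))
}

.require_cols <- function(df, cols, what = "metadata") {
  missing <- setdiff(cols, colnames(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Cohort factor with MC as the reference level when present.
.cohort_factor <- function(x, reference = "MC") {
  x <- as.character(x)
  lev <- unique(x)
  if (reference %in% lev) lev <- c(reference, sort(setdiff(lev, reference)))
  factor(x, levels = lev)
}
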