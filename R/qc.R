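#' Cell quality-control thresholds
#'
#' Defaults follow the standard post-droplet-calling filters for colonic
#' mucosa: remove cells with fewer than 200 detected genes or more than 20%
#' mitochondrial UMI content. Boundary convention: exactly `min_genes`
#' detected genes is retained; exactly `max_mito_fraction` mitochondrial
#' content is retained.
#'
#' @param min_genes Minimum detected (nonzero) genes per cell.
#' @param max_mito_fraction Maximum mitochondrial UMI fraction, in \[0, 1\].
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_mito_fraction = 0.20,
                          mito_prefix = "MT-") {
  stopifnot(min_genes >= 0, max_mito_fraction >= 0, max_mito_fraction <= 1,
            is.character(mito_prefix), nzchar(mito_prefix))
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Mitochondrial UMI fraction of one cell
#'
#' Sum of counts over genes whose name starts with `mito_prefix`, divided by
#' the cell's total counts.
#'
#' @param cell_counts Numeric vector of gene counts for one cell.
#' @param gene_names Gene names aligned with `cell_counts` (defaults to
#'   `names(cell_counts)`).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return Fraction in \[0, 1\].
#' @export
mito_fraction <- function(cell_counts, gene_names = names(cell_counts),
                          mito_prefix = "MT-") {
  stopifnot(length(cell_counts) == length(gene_names))
  total <- sum(cell_counts)
  if (total <= 0) {
    stop("mito_fraction is undefined for a cell with zero total counts; remove it upstream",
         call. = FALSE)
  }
  sum(cell_counts[startsWith(gene_names, mito_prefix)]) / total
}

#' Filter cells on detected genes and mitochondrial content
#'
#' Retains cells with at least `min_genes` detected genes AND mitochondrial
#' UMI fraction at most `max_mito_fraction`. A cell failing both rules is
#' tallied in both removal counts. Cohort-level manual exclusions (e.g. an
#' overloaded library, or clusters defined only by mitochondrial genes) are
#' applied via `exclude_barcodes`, not automated.
#'
#' @param dataset A `SingleCellExperiment` with a `counts` assay.
#' @param thresholds A [qc_thresholds()].
#' @param exclude_barcodes Optional character vector of barcodes to drop
#'   before filtering (manual exclusion list).
#' @return List with `dataset` (filtered) and `report` (a `qc_report`:
#'   tallies plus the upstream droplet-calling provenance note).
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds(),
                         exclude_barcodes = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- .counts(dataset)
  if (ncol(counts) == 0L) stop("dataset has no cells", call. = FALSE)
  if (is.null(rownames(counts))) stop("gene names are required", call. = FALSE)

  n_excluded <- 0L
  if (!is.null(exclude_barcodes)) {
    keep0 <- !(colnames(counts) %in% exclude_barcodes)
    n_excluded <- sum(!keep0)
    dataset <- dataset[, keep0]
    counts <- counts[, keep0, drop = FALSE]
  }

  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[startsWith(rownames(counts),
                                            thresholds$mito_prefix), ,
                                 drop = FALSE])
  frac <- ifelse(total > 0, mito / total, NA_real_)

  low_genes <- detected < thresholds$min_genes
  high_mito <- !is.na(frac) & frac > thresholds$max_mito_fraction
  keep <- !low_genes & !high_mito
  if (!any(keep)) warning("no cells pass the QC filters; returning an empty dataset")

  report <- structure(list(
    cells_in = ncol(counts),
    cells_excluded_manually = n_excluded,
    cells_removed_low_genes = sum(low_genes),
    cells_removed_high_mito = sum(high_mito),
    cells_out = sum(keep),
    thresholds = thresholds,
    provenance = paste("Droplet calling upstream of this filter: EmptyDrops",
                       "with lower UMI bound 100; barcodes kept above the",
                       "knee or at FDR below 0.01 (recorded as provenance",
                       "only, not recomputed here).")),
    class = "qc_report")
  list(dataset = dataset[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Cell QC report\n")
  cat(sprintf("  cells in:               %d\n", x$cells_in))
  if (x$cells_excluded_manually > 0L) {
    cat(sprintf("  manually excluded:      %d\n", x$cells_excluded_manually))
  }
  cat(sprintf("  removed, < %d genes:   %d\n",
              x$thresholds$min_genes, x$cells_removed_low_genes))
  cat(sprintf("  removed, > %.0f%% mito:   %d\n",
              100 * x$thresholds$max_mito_fraction, x$cells_removed_high_mito))
  cat(sprintf("  cells out:              %d\n", x$cells_out))
  invisible(x)
}
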