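#' Write a cell dataset as Matrix-Market triplet files
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a `cells.csv`
#' metadata table into `dir` (created if needed).
#'
#' @param dataset A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cell_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .counts(dataset)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.csv(.cell_meta(dataset), file.path(dir, "cells.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cell dataset written by [write_cell_dataset()]
#'
#' Also reads the bare 10X-style layout (`matrix.mtx` + `features.tsv` +
#' `barcodes.tsv`) when no `cells.csv` is present, in which case the metadata
#' holds barcodes only.
#'
#' @param dir Directory containing the files.
#' @return A `SingleCellExperiment`.
#' @export
read_cell_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cells.csv")
  meta <- if (file.exists(meta_path)) {
    read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  }
  if (!identical(as.character(meta$barcode), colnames(counts))) {
    stop("cells.csv barcodes do not match the matrix columns", call. = FALSE)
  }
  rownames(meta) <- meta$barcode
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
}

#' Read a filtered-contig annotation table
#'
#' Reads the 10X-style `filtered_contig_annotations.csv` dialect. Column
#' presence is validated; extra columns pass through.
#'
#' @param path CSV file path.
#' @return Data frame of contig records.
#' @export
read_contigs <- function(path) {
  contigs <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(contigs, c("barcode", "chain", "cdr3", "productive",
                           "high_confidence"), "contig file")
  contigs
}

#' Write per-patient contig tables
#'
#' One `<patient>_filtered_contig_annotations.csv` per patient.
#'
#' @param contigs Named list of per-patient contig data frames, as produced
#'   by [generate_repertoire()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_contigs <- function(contigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (patient in names(contigs)) {
    write.csv(contigs[[patient]],
              file.path(dir, sprintf("%s_filtered_contig_annotations.csv",
                                     patient)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a histology count table
#'
#' @param path CSV with columns `image_id, patient, cohort, probe, count,
#'   dapi_total` (plus optional `compartment`).
#' @return Data frame of image counts.
#' @export
read_histology_counts <- function(path) {
  counts <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(counts, c("image_id", "patient", "cohort", "probe", "count",
                          "dapi_total"), "histology count file")
  if (any(counts$count < 0) || any(counts$dapi_total <= 0)) {
    stop("counts must be nonnegative and dapi_total positive", call. = FALSE)
  }
  counts
}

#' Export a pseudobulk count table for external DE engines
#'
#' Writes the summed counts as CSV (genes x groups) plus the group metadata,
#' the layout expected by published GLM pipelines.
#'
#' @param pb A `pseudobulk_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pseudobulk <- function(pb, dir) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(pb$counts),
            file.path(dir, "pseudobulk_counts.csv"), row.names = TRUE)
  write.csv(pb$groups, file.path(dir, "pseudobulk_groups.csv"),
            row.names = FALSE)
  invisible(dir)
}
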