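#' Curated compartment marker sets
#'
#' The three curated marker lists used to assign clusters to the immune,
#' epithelial and stromal compartments of intestinal mucosa. The list order
#' (immune, epithelial, stromal) is also the deterministic tie-break order
#' for equal scores. `CD16` is not a current HGNC symbol; [score_clusters()]
#' resolves it to `FCGR3A` via [marker_aliases()] when absent from the data.
#'
#' @return Named list of character vectors.
#' @export
marker_sets <- function() {
  list(
    immune = c("CD52", "CD2", "CD3D", "CD3G", "CD3E", "CD79A", "CD79B",
               "CD14", "CD16", "CD68", "CD83", "CSF1R", "FCER1G"),
    epithelial = c("EPCAM", "KRT8", "KRT18"),
    stromal = c("COL1A1", "COL1A2", "COL6A1", "COL6A2", "VWF", "PLVAP",
                "CDH5", "S100B")
  )
}

#' Marker-name alias table
#'
#' Legacy marker names mapped to current HGNC symbols, applied by
#' [score_clusters()] when the legacy name is absent from the expression
#' matrix but the modern symbol is present.
#'
#' @return Named character vector (legacy name -> HGNC symbol).
#' @export
marker_aliases <- function() {
  c(CD16 = "FCGR3A")
}

#' Library-size normalization with log transform
#'
#' Scales each cell to `scale_total` total counts, then applies `log1p`.
#' Zero counts map to zero; a cell's normalized vector is invariant to
#' uniform scaling of its counts.
#'
#' @param dataset A `SingleCellExperiment` with a `counts` assay, or a
#'   gene x cell matrix.
#' @param scale_total Target total per cell (counts-per-10,000 by default).
#' @return A sparse gene x cell matrix of `log1p`-transformed scaled counts.
#' @export
normalize_log <- function(dataset, scale_total = 1e4) {
  counts <- if (methods::is(dataset, "SummarizedExperiment")) {
    .counts(dataset)
  } else {
    .sparse(dataset)
  }
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    stop("cells with zero total counts (run QC first): ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" ... and %d more", length(bad) - 5L),
         call. = FALSE)
  }
  scaled <- counts %*% Matrix::Diagonal(x = scale_total / totals)
  dimnames(scaled) <- dimnames(counts)
  out <- scaled
  out@x <- log1p(out@x)
  out
}

#' Score clusters against compartment marker sets
#'
#' For each cluster and compartment, the score is the mean over the
#' compartment's matched marker genes of the mean normalized expression over
#' the cluster's cells. Each cluster is assigned to the compartment with the
#' maximum score; exact ties fall back to the marker-list order with a
#' warning. Marker genes absent from the matrix are resolved through
#' `aliases`, then logged and skipped; a compartment with no matched genes is
#' an error.
#'
#' @param normalized Gene x cell normalized matrix (see [normalize_log()]).
#' @param labeling Cluster labels: a `cluster_labeling` or a vector named by
#'   cell barcode covering every column of `normalized`.
#' @param markers Named list of marker-gene vectors (default [marker_sets()]).
#' @param aliases Named character vector of marker-name aliases.
#' @return A `compartment_scores` object: `scores` (cluster x compartment
#'   matrix), `assignment`, `margin` (top score minus runner-up) and the
#'   labeling used.
#' @export
score_clusters <- function(normalized, labeling, markers = marker_sets(),
                           aliases = marker_aliases()) {
  labels <- if (inherits(labeling, "cluster_labeling")) {
    labeling$labels
  } else {
    labeling
  }
  if (is.null(names(labels))) {
    stopifnot(length(labels) == ncol(normalized))
    names(labels) <- colnames(normalized)
  }
  unlabeled <- setdiff(colnames(normalized), names(labels))
  if (length(unlabeled) > 0L) {
    stop(sprintf("%d cells have no cluster label", length(unlabeled)),
         call. = FALSE)
  }
  labels <- labels[colnames(normalized)]

  resolve <- function(genes) {
    miss <- !(genes %in% rownames(normalized))
    aliased <- genes %in% names(aliases) &
      unname(aliases[genes]) %in% rownames(normalized)
    swap <- miss & aliased
    if (any(swap)) {
      message("marker alias applied: ",
              paste(sprintf("%s -> %s", genes[swap], aliases[genes[swap]]),
                    collapse = ", "))
      genes[swap] <- aliases[genes[swap]]
    }
    absent <- setdiff(genes, rownames(normalized))
    if (length(absent) > 0L) {
      message("marker genes absent from the matrix, skipped: ",
              paste(absent, collapse = ", "))
    }
    intersect(genes, rownames(normalized))
  }
  matched <- lapply(markers, resolve)
  empty <- names(matched)[lengths(matched) == 0L]
  if (length(empty) > 0L) {
    stop("no marker genes matched for compartment(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }

  cluster_ids <- sort(unique(as.character(labels)))
  # cluster-mean expression of every needed gene, then mean over markers
  need <- unique(unlist(matched, use.names = FALSE))
  sub <- normalized[need, , drop = FALSE]
  grp <- factor(as.character(labels), levels = cluster_ids)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), length(cluster_ids)))
  cluster_mean <- as.matrix(sub %*% ind) /
    rep(tabulate(grp, length(cluster_ids)), each = nrow(sub))
  colnames(cluster_mean) <- cluster_ids

  scores <- vapply(matched, function(genes) {
    colMeans(cluster_mean[genes, , drop = FALSE])
  }, numeric(length(cluster_ids)))
  scores <- matrix(scores, nrow = length(cluster_ids),
                   dimnames = list(cluster_ids, names(matched)))

  assignment <- apply(scores, 1L, function(s) names(matched)[which.max(s)])
  margin <- apply(scores, 1L, function(s) {
    s <- sort(s, decreasing = TRUE)
    if (length(s) > 1L) s[1] - s[2] else s[1]
  })
  ties <- apply(scores, 1L, function(s) sum(s == max(s)) > 1L)
  if (any(ties)) {
    warning("tied compartment scores for cluster(s) ",
            paste(cluster_ids[ties], collapse = ", "),
            "; assigned by marker-list order")
  }
  structure(list(scores = scores, assignment = assignment, margin = margin,
                 labels = labels, compartments = names(matched)),
            class = "compartment_scores")
}

#' Split a dataset into compartment-level datasets
#'
#' Partitions the cells of `dataset` by the compartment assigned to their
#' cluster. Every compartment in the score table gets a key, possibly with an
#' empty dataset; every input cell appears in exactly one output.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param scores A `compartment_scores` from [score_clusters()] covering all
#'   clusters of the dataset's cells.
#' @return Named list of `SingleCellExperiment` objects, one per compartment.
#' @export
split_dataset <- function(dataset, scores) {
  stopifnot(inherits(scores, "compartment_scores"))
  labels <- scores$labels
  missing <- setdiff(colnames(dataset), names(labels))
  if (length(missing) > 0L) {
    stop(sprintf("%d cells are not covered by the score table",
                 length(missing)), call. = FALSE)
  }
  cell_comp <- scores$assignment[as.character(labels[colnames(dataset)])]
  out <- lapply(scores$compartments, function(comp) {
    dataset[, which(cell_comp == comp)]
  })
  names(out) <- scores$compartments
  out
}

#' @export
print.compartment_scores <- function(x, ...) {
  cat(sprintf("Compartment scores for %d clusters\n", nrow(x$scores)))
  print(round(x$scores, 4))
  cat("assignment:\n")
  print(x$assignment)
  invisible(x)
}
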