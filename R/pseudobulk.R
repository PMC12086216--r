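#' Aggregate single-cell counts to pseudobulk profiles
#'
#' Sums raw counts per (patient, cell type) group in exact integer
#' arithmetic, keeping only groups with at least `min_cells` cells.
#'
#' @param dataset A `SingleCellExperiment` whose cells carry `patient`,
#'   `cohort` and cell-type metadata.
#' @param min_cells Minimum cells per group (groups with fewer are dropped).
#' @param cell_type_column Metadata column naming the cell type.
#' @return A `pseudobulk_matrix`: `counts` (gene x group dense integer
#'   matrix) and `groups` (group, patient, cell_type, cohort, n_cells).
#' @export
pb_aggregate <- function(dataset, min_cells = 5L, cell_type_column = "cell_type") {
  counts <- .counts(dataset)
  meta <- .cell_meta(dataset)
  .require_cols(meta, c("patient", "cohort", cell_type_column))
  patient <- as.character(meta$patient)
  cell_type <- as.character(meta[[cell_type_column]])
  group <- paste(patient, cell_type, sep = "|")
  grp <- factor(group)
  n_cells <- tabulate(grp, nlevels(grp))
  keep_levels <- levels(grp)[n_cells >= min_cells]
  if (length(keep_levels) == 0L) {
    stop(sprintf("no (patient, cell type) group has at least %d cells",
                 min_cells), call. = FALSE)
  }
  keep <- group %in% keep_levels
  grp2 <- factor(group[keep], levels = keep_levels)
  ind <- Matrix::sparseMatrix(i = which(keep), j = as.integer(grp2), x = 1,
                              dims = c(ncol(counts), length(keep_levels)))
  pb <- as.matrix(counts %*% ind)
  storage.mode(pb) <- "integer"
  colnames(pb) <- keep_levels

  first <- match(keep_levels, group)
  groups <- data.frame(group = keep_levels,
                       patient = patient[first],
                       cell_type = cell_type[first],
                       cohort = as.character(meta$cohort)[first],
                       n_cells = tabulate(grp, nlevels(grp))[match(keep_levels,
                                                                   levels(grp))],
                       stringsAsFactors = FALSE)
  structure(list(counts = pb, groups = groups, min_cells = as.integer(min_cells)),
            class = "pseudobulk_matrix")
}

#' Log2 counts-per-million transform of a pseudobulk matrix
#'
#' Scales each group column to one million total counts, then applies
#' `log2(x + pseudocount)`.
#'
#' @param pb A `pseudobulk_matrix` or a gene x group count matrix.
#' @param pseudocount Added before the log (default 1, so zeros map to zero).
#' @return Gene x group numeric matrix of log2-CPM values.
#' @export
cpm_log <- function(pb, pseudocount = 1) {
  m <- if (inherits(pb, "pseudobulk_matrix")) pb$counts else as.matrix(pb)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero-sum pseudobulk column(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(m, 2L, totals, "/") * 1e6 + pseudocount)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Midranks for ties; exact null when `min(n_a, n_b) <= 8` and there are no
#' ties, normal approximation with tie-corrected variance otherwise. When
#' every value in both groups is identical the comparison is degenerate and
#' `p = 1` is returned with a flag.
#'
#' @param values_a,values_b Nonempty numeric vectors.
#' @return List: `statistic` (Mann-Whitney U for the first group), `p`
#'   (two-sided), `degenerate`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p = 1, degenerate = TRUE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && min(length(values_a), length(values_b)) <= 8L
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = min(ht$p.value, 1),
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input order is preserved; adjusted values are monotone in the sorted order
#' and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Cohort differential expression on pseudobulk profiles
#'
#' For one cell type and a cohort pair, compares per-patient pseudobulk
#' log2-CPM values gene by gene with the rank-sum test; the log2 fold change
#' is the difference of per-side mean log2-CPM. BH adjustment is applied over
#' the genes of this comparison. A gene with identical values on both sides
#' (e.g. absent everywhere) gets `log2fc = 0, p = 1`.
#'
#' @param pb A `pseudobulk_matrix` from [pb_aggregate()].
#' @param cell_type Cell type whose patient groups are compared.
#' @param cohort_pair Length-2 character vector; fold changes are
#'   `cohort_pair[1]` minus `cohort_pair[2]`.
#' @param pseudocount Passed to [cpm_log()].
#' @return Data frame of class `de_result`: `gene, cell_type, comparison,
#'   log2fc, stat, p, p_adj, mean_a, mean_b`.
#' @export
cohort_de <- function(pb, cell_type, cohort_pair = c("MC", "chronic_diarrhea"),
                      pseudocount = 1) {
  stopifnot(inherits(pb, "pseudobulk_matrix"), length(cohort_pair) == 2L)
  g <- pb$groups
  side_a <- g$group[g$cell_type == cell_type & g$cohort == cohort_pair[1]]
  side_b <- g$group[g$cell_type == cell_type & g$cohort == cohort_pair[2]]
  for (side in list(c(cohort_pair[1], length(side_a)),
                    c(cohort_pair[2], length(side_b)))) {
    if (as.integer(side[2]) < 2L) {
      stop(sprintf("cell type '%s' has fewer than 2 patient groups in cohort '%s'",
                   cell_type, side[1]), call. = FALSE)
    }
  }
  lcpm <- cpm_log(pb$counts[, c(side_a, side_b), drop = FALSE],
                  pseudocount = pseudocount)
  a <- lcpm[, side_a, drop = FALSE]
  b <- lcpm[, side_b, drop = FALSE]

  n_genes <- nrow(lcpm)
  stat <- p <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    t <- rank_sum_test(a[i, ], b[i, ])
    stat[i] <- t$statistic
    p[i] <- t$p
  }
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  out <- data.frame(gene = rownames(lcpm), cell_type = cell_type,
                    comparison = paste(cohort_pair, collapse = " vs "),
                    log2fc = mean_a - mean_b, stat = stat, p = p,
                    p_adj = bh_adjust(p),
                    mean_a = mean_a, mean_b = mean_b,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Cluster-marker differential expression at the single-cell level
#'
#' Compares each gene's normalized expression in one cluster against all
#' other cells of the supplied background (e.g. all T cells, or all immune
#' cells) with the rank-sum test, BH-adjusted over genes. Candidate ranking
#' thresholds (minimum absolute log fold change, minimum percent expressed)
#' are configuration values.
#'
#' @param normalized Gene x cell normalized matrix (see [normalize_log()]).
#' @param labeling Cluster labels covering the columns of `normalized`.
#' @param cluster Cluster whose markers are sought.
#' @param min_abs_lfc,min_pct Filters applied to the returned candidate flag
#'   (natural-log fold change of mean expression; fraction of in-cluster
#'   cells expressing the gene).
#' @return Data frame: `gene, log_fc, pct_in, pct_out, stat, p, p_adj,
#'   candidate`, ordered by `p_adj`.
#' @export
cluster_markers <- function(normalized, labeling, cluster,
                            min_abs_lfc = 0.25, min_pct = 0.10) {
  labels <- if (inherits(labeling, "cluster_labeling")) labeling$labels else labeling
  if (is.null(names(labels))) {
    stopifnot(length(labels) == ncol(normalized))
    names(labels) <- colnames(normalized)
  }
  labels <- labels[colnames(normalized)]
  in_cl <- which(as.character(labels) == as.character(cluster))
  out_cl <- which(as.character(labels) != as.character(cluster))
  if (length(in_cl) < 2L || length(out_cl) < 2L) {
    stop("both the cluster and the background need at least 2 cells",
         call. = FALSE)
  }
  m <- as.matrix(normalized)
  stat <- p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    t <- rank_sum_test(m[i, in_cl], m[i, out_cl])
    stat[i] <- t$statistic
    p[i] <- t$p
  }
  log_fc <- log(rowMeans(m[, in_cl, drop = FALSE]) + 1e-9) -
    log(rowMeans(m[, out_cl, drop = FALSE]) + 1e-9)
  pct_in <- rowMeans(m[, in_cl, drop = FALSE] > 0)
  pct_out <- rowMeans(m[, out_cl, drop = FALSE] > 0)
  out <- data.frame(gene = rownames(m), log_fc = log_fc,
                    pct_in = pct_in, pct_out = pct_out,
                    stat = stat, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$candidate <- abs(out$log_fc) >= min_abs_lfc & out$pct_in >= min_pct &
    out$p_adj < 0.05
  out[order(out$p_adj, out$p), ]
}
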