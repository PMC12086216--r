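.is_true <- function(x) {
  if (is.logical(x)) return(x & !is.na(x))
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Merge a patient's TCR contigs into clonotypes
#'
#' Filters contigs to those flagged both productive and high-confidence,
#' then defines each barcode's clonotype by its set of retained CDR3
#' amino-acid sequences. Identical CDR3 sets -- including across libraries of
#' the same patient -- collapse to a single clonotype with pooled member
#' cells, which receives a new patient-scoped clonotype ID. Duplicate
#' `(barcode, chain, cdr3)` rows are deduplicated with a warning. Merging is
#' idempotent.
#'
#' @param contigs Data frame in the 10X filtered-contig dialect; columns
#'   `barcode, chain, cdr3, productive, high_confidence` are required.
#' @param patient Patient ID.
#' @param cohort Optional cohort label carried on the repertoire.
#' @param clusters Optional named vector (barcode -> cell cluster) from the
#'   expression analysis.
#' @return A `repertoire`: `patient`, `cohort`, `clonotypes` (clonotype_id,
#'   cdr3_key, n_cells) and `cells` (barcode, clonotype_id, cluster).
#' @export
merge_clonotypes <- function(contigs, patient, cohort = NA_character_,
                             clusters = NULL) {
  .require_cols(contigs, c("barcode", "chain", "cdr3", "productive",
                           "high_confidence"), "contig table")
  dup <- duplicated(contigs[, c("barcode", "chain", "cdr3")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (barcode, chain, cdr3) contig row(s) removed",
                    sum(dup)))
    contigs <- contigs[!dup, , drop = FALSE]
  }
  keep <- .is_true(contigs$productive) & .is_true(contigs$high_confidence) &
    nzchar(as.character(contigs$cdr3))
  contigs <- contigs[keep, , drop = FALSE]

  key_of <- vapply(split(as.character(contigs$cdr3), contigs$barcode),
                   function(s) paste(sort(unique(s)), collapse = ";"), "")
  keys <- unique(key_of)
  ids <- setNames(sprintf("%s_ct%04d", patient, seq_along(keys)), keys)
  cells <- data.frame(barcode = names(key_of),
                      clonotype_id = unname(ids[key_of]),
                      stringsAsFactors = FALSE, row.names = NULL)
  cells$cluster <- if (!is.null(clusters)) {
    unname(clusters[cells$barcode])
  } else {
    rep(NA_character_, nrow(cells))
  }
  sizes <- table(cells$clonotype_id)
  clonotypes <- data.frame(clonotype_id = unname(ids),
                           cdr3_key = keys,
                           n_cells = as.integer(sizes[unname(ids)]),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(patient = patient, cohort = cohort,
                 clonotypes = clonotypes, cells = cells),
            class = "repertoire")
}

#' Clonotype frequency table for one patient
#'
#' Cell counts and proportions of the patient's clonotype-bearing cells
#' (cells lacking a productive TCR were never admitted to the repertoire, so
#' proportions sum to 1). One row per clonotype, ready for a stacked-bar
#' export.
#'
#' @param rep A `repertoire` from [merge_clonotypes()].
#' @return Data frame: `clonotype_id, cdr3_key, n_cells, proportion`, sorted
#'   by decreasing size.
#' @export
clonotype_frequencies <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clonotypes
  if (nrow(cl) == 0L) stop("empty repertoire", call. = FALSE)
  cl$proportion <- cl$n_cells / sum(cl$n_cells)
  cl[order(-cl$n_cells, cl$clonotype_id), ]
}

#' Shannon diversity of a clonotype frequency distribution
#'
#' `H = -sum(p_i * ln p_i)` with natural logarithm, over per-clonotype cell
#' counts. A single clonotype gives 0; K equally sized clonotypes give
#' `ln K`.
#'
#' @param freqs A `repertoire`, a frequency table from
#'   [clonotype_frequencies()], or a numeric vector of clonotype cell counts
#'   (or proportions).
#' @return Shannon diversity (nats).
#' @export
shannon_diversity <- function(freqs) {
  x <- if (inherits(freqs, "repertoire")) {
    freqs$clonotypes$n_cells
  } else if (is.data.frame(freqs)) {
    freqs$n_cells
  } else {
    freqs
  }
  x <- as.numeric(x)
  if (length(x) == 0L || sum(x) <= 0) {
    stop("need a nonempty frequency vector with positive total", call. = FALSE)
  }
  if (any(x < 0)) stop("negative frequencies", call. = FALSE)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Expanded clonotypes of a repertoire
#'
#' A clonotype is expanded when assigned to at least 2 cells.
#'
#' @param rep A `repertoire`.
#' @return Character vector of expanded clonotype IDs (possibly empty).
#' @export
classify_expanded <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  rep$clonotypes$clonotype_id[rep$clonotypes$n_cells >= 2L]
}

# Per-clonotype cluster occupancy for a list of repertoires. Cells without a
# cluster label are excluded (count logged). Clonotype IDs are patient-scoped
# so pooling across repertoires never collides.
.clonotype_occupancy <- function(reps) {
  rows <- lapply(reps, function(rep) {
    stopifnot(inherits(rep, "repertoire"))
    cells <- rep$cells
    n_unlab <- sum(is.na(cells$cluster))
    if (n_unlab > 0L) {
      message(sprintf("%s: %d cell(s) without a cluster label excluded",
                      rep$patient, n_unlab))
      cells <- cells[!is.na(cells$cluster), , drop = FALSE]
    }
    if (nrow(cells) == 0L) return(NULL)
    occ <- tapply(as.character(cells$cluster), cells$clonotype_id,
                  function(cl) sort(unique(cl)), simplify = FALSE)
    sizes <- setNames(rep$clonotypes$n_cells, rep$clonotypes$clonotype_id)
    data.frame(clonotype_id = names(occ),
               patient = rep$patient, cohort = rep$cohort,
               expanded = unname(sizes[names(occ)]) >= 2L,
               n_clusters = lengths(occ),
               clusters = I(unname(occ)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Cluster-by-cluster clonotype sharing matrix
#'
#' Off-diagonal entry (i, j): number of expanded clonotypes with at least one
#' cell in cluster i and at least one in cluster j, pooled over the supplied
#' repertoires (typically one cohort). Diagonal entry (i, i): total number of
#' unique clonotypes (expanded or not) observed in cluster i.
#'
#' @param reps List of `repertoire` objects with cell cluster labels.
#' @param clusters Cluster label set ordering the matrix (default: all
#'   observed).
#' @return Symmetric integer matrix, clusters x clusters.
#' @export
sharing_matrix <- function(reps, clusters = NULL) {
  occ <- .clonotype_occupancy(reps)
  if (is.null(occ)) stop("no cluster-labeled cells in any repertoire",
                         call. = FALSE)
  if (is.null(clusters)) {
    clusters <- sort(unique(unlist(occ$clusters, use.names = FALSE)))
  }
  m <- matrix(0L, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  for (r in seq_len(nrow(occ))) {
    cl <- intersect(occ$clusters[[r]], clusters)
    if (length(cl) == 0L) next
    m[cbind(cl, cl)] <- m[cbind(cl, cl)] + 1L
    if (occ$expanded[r] && length(cl) >= 2L) {
      pairs <- t(utils::combn(cl, 2L))
      m[pairs] <- m[pairs] + 1L
      m[pairs[, c(2L, 1L), drop = FALSE]] <-
        m[pairs[, c(2L, 1L), drop = FALSE]] + 1L
    }
  }
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one (within relative tolerance 1e-7). A zero margin makes the
#' table degenerate and returns p = 1.
#'
#' @param table 2x2 matrix (or length-4 vector, filled column-wise) of
#'   nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("table must contain 4 nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  min(fisher.test(m)$p.value, 1)
}

#' Cohort comparison of clonotype sharing per cluster
#'
#' Implements the dual-comparison sharing test. For each cluster the expanded
#' clonotypes observed in it (pooled across a cohort's patients) are split
#' into shared (present in at least two distinct clusters) vs unique
#' (confined to this cluster). Two 2x2 contingency tables per cluster compare
#' the reference cohort against each comparison cohort; Fisher p-values are
#' BH-adjusted across testable clusters within each comparison, and a cluster
#' is flagged only when the adjusted p-value is below `alpha` in both
#' comparisons. A cluster with no expanded clonotypes in one of a table's
#' cohorts is flagged not-testable and excluded from that comparison's BH
#' family.
#'
#' @param reps List of `repertoire` objects (all cohorts together), each with
#'   a `cohort` and cell cluster labels.
#' @param clusters Cluster set to test (default: all observed).
#' @param reference Reference cohort (default `"MC"`).
#' @param comparisons Cohorts compared against the reference.
#' @param alpha Significance level on the adjusted p-values.
#' @return A `sharing_result`: `tests` (one row per cluster x comparison:
#'   counts, p, p_adj, testable) and `flags` (per cluster:
#'   `dual_significant`).
#' @export
sharing_test <- function(reps, clusters = NULL, reference = "MC",
                         comparisons = c("chronic_diarrhea", "unaffected"),
                         alpha = 0.05) {
  occ <- .clonotype_occupancy(reps)
  if (is.null(occ)) stop("no cluster-labeled cells in any repertoire",
                         call. = FALSE)
  cohorts_seen <- unique(occ$cohort)
  missing <- setdiff(c(reference, comparisons), cohorts_seen)
  if (length(missing) > 0L) {
    stop("cohort(s) absent from the repertoires: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(clusters)) {
    clusters <- sort(unique(unlist(occ$clusters, use.names = FALSE)))
  }
  occ <- occ[occ$expanded, , drop = FALSE]

  tally <- function(cohort, cluster) {
    rows <- occ$cohort == cohort &
      vapply(occ$clusters, function(cl) cluster %in% cl, TRUE)
    shared <- sum(rows & occ$n_clusters >= 2L)
    unique_ <- sum(rows & occ$n_clusters == 1L)
    c(shared = shared, unique = unique_)
  }

  tests <- list()
  for (comp in comparisons) {
    for (cl in clusters) {
      ref_t <- tally(reference, cl)
      oth_t <- tally(comp, cl)
      testable <- sum(ref_t) > 0L && sum(oth_t) > 0L
      p <- if (testable) {
        fisher_exact_2x2(rbind(ref_t, oth_t))
      } else {
        NA_real_
      }
      tests[[length(tests) + 1L]] <- data.frame(
        cluster = cl, comparison = comp,
        ref_shared = ref_t[["shared"]], ref_unique = ref_t[["unique"]],
        other_shared = oth_t[["shared"]], other_unique = oth_t[["unique"]],
        p = p, testable = testable, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- NA_real_
  for (comp in comparisons) {
    fam <- which(tests$comparison == comp & tests$testable)
    if (length(fam) > 0L) tests$p_adj[fam] <- bh_adjust(tests$p[fam])
  }

  flags <- data.frame(cluster = clusters, stringsAsFactors = FALSE)
  flags$dual_significant <- vapply(clusters, function(cl) {
    rows <- tests[tests$cluster == cl, ]
    all(rows$testable) && all(rows$p_adj < alpha)
  }, TRUE)
  structure(list(tests = tests, flags = flags, reference = reference,
                 comparisons = comparisons, alpha = alpha),
            class = "sharing_result")
}

#' @export
print.sharing_result <- function(x, ...) {
  cat(sprintf("Clonotype sharing test (%s vs %s), alpha = %g\n",
              x$reference, paste(x$comparisons, collapse = " / "), x$alpha))
  print(x$tests, row.names = FALSE)
  sig <- x$flags$cluster[x$flags$dual_significant]
  cat("dual-significant cluster(s):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
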