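#' Per-patient cell-type proportion table
#'
#' Counts cells per (patient, cell type) and divides by a configurable
#' denominator:
#' \describe{
#'   \item{`all_immune`}{all cells of the patient present in `metadata`
#'     (callers pass an already-subset compartment, e.g. immune cells).}
#'   \item{`parent_lineage`}{all cells of the patient sharing the cell type's
#'     parent lineage; requires `parents` (e.g. every CD8 subset relative to
#'     all CD8 T cells).}
#'   \item{`cycling_only`}{only the cell types in `denominator_types` (e.g.
#'     cycling subsets relative to all cycling cells).}
#'   \item{`custom`}{an explicit `denominator_types` set.}
#' }
#' Patients with an empty denominator are emitted with `NA` proportions and
#' logged, mirroring the convention that patients with no cells in an
#' identity class are not plotted.
#'
#' @param metadata Data frame with one row per cell: `patient`, `cohort`, and
#'   the cell-type column.
#' @param cell_type_column Name of the cell-type column.
#' @param denominator_scope One of `all_immune`, `parent_lineage`,
#'   `cycling_only`, `custom`.
#' @param denominator_types Cell types forming numerator and denominator for
#'   the `cycling_only` / `custom` scopes.
#' @param parents Named character vector mapping cell type -> parent lineage
#'   (required for `parent_lineage`).
#' @return Data frame of class `proportion_table`: `patient, cohort,
#'   cell_type, n, denominator, proportion` (zero-count combinations
#'   included).
#' @export
per_patient_proportions <- function(metadata,
                                    cell_type_column = "cell_type",
                                    denominator_scope = c("all_immune",
                                                          "parent_lineage",
                                                          "cycling_only",
                                                          "custom"),
                                    denominator_types = NULL,
                                    parents = NULL) {
  denominator_scope <- match.arg(denominator_scope)
  .require_cols(metadata, c("patient", "cohort", cell_type_column))
  df <- data.frame(patient = as.character(metadata$patient),
                   cohort = as.character(metadata$cohort),
                   cell_type = as.character(metadata[[cell_type_column]]),
                   stringsAsFactors = FALSE)

  pat <- unique(df[, c("patient", "cohort")])
  if (denominator_scope %in% c("cycling_only", "custom")) {
    if (is.null(denominator_types)) {
      stop(sprintf("denominator_types is required for scope '%s'",
                   denominator_scope), call. = FALSE)
    }
    df <- df[df$cell_type %in% denominator_types, , drop = FALSE]
    types <- denominator_types
  } else {
    types <- sort(unique(df$cell_type))
  }
  if (denominator_scope == "parent_lineage") {
    if (is.null(parents)) {
      stop("parents mapping is required for scope 'parent_lineage'",
           call. = FALSE)
    }
    unmapped <- setdiff(types, names(parents))
    if (length(unmapped) > 0L) {
      stop("cell type(s) without a parent lineage: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
  }

  grid <- merge(pat, data.frame(cell_type = types), by = NULL)
  cnt <- as.data.frame(table(patient = df$patient, cell_type = df$cell_type),
                       stringsAsFactors = FALSE)
  names(cnt)[3] <- "n"
  out <- merge(grid, cnt, by = c("patient", "cell_type"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L

  denom_group <- if (denominator_scope == "parent_lineage") {
    unname(parents[out$cell_type])
  } else {
    rep("all", nrow(out))
  }
  key <- paste(out$patient, denom_group)
  denom <- tapply(out$n, key, sum)
  out$denominator <- as.integer(denom[key])
  out$n <- as.integer(out$n)
  out$proportion <- ifelse(out$denominator > 0, out$n / out$denominator,
                           NA_real_)
  empty <- unique(out$patient[out$denominator == 0])
  if (length(empty) > 0L) {
    message("patients with no cells in the denominator (proportion = NA): ",
            paste(empty, collapse = ", "))
  }
  out <- out[order(out$patient, out$cell_type),
             c("patient", "cohort", "cell_type", "n", "denominator",
               "proportion")]
  rownames(out) <- NULL
  attr(out, "denominator_scope") <- denominator_scope
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Cohort enrichment stack per cell type
#'
#' For every cell type, pools cells across patients and computes each
#' cohort's share of the pooled total (columns scale to 100%), retaining each
#' patient's fractional contribution to its cohort's share (the "varying
#' transparency" breakdown of a stacked enrichment column).
#'
#' @param proportions A `proportion_table` from [per_patient_proportions()].
#' @return Data frame: `cell_type, cohort, patient, n, cohort_share,
#'   patient_contribution`; cohort shares sum to 1 within each cell type
#'   (with cells present), patient contributions to 1 within each
#'   (cell type, cohort) with cells present.
#' @export
enrichment_stack <- function(proportions) {
  stopifnot(nrow(proportions) > 0L)
  .require_cols(proportions, c("patient", "cohort", "cell_type", "n"),
                "proportion table")
  df <- as.data.frame(proportions)
  total_type <- tapply(df$n, df$cell_type, sum)
  key_tc <- paste(df$cell_type, df$cohort)
  total_tc <- tapply(df$n, key_tc, sum)
  df$cohort_share <- as.numeric(ifelse(total_type[df$cell_type] > 0,
                                       total_tc[key_tc] /
                                         total_type[df$cell_type],
                                       NA_real_))
  df$patient_contribution <- as.numeric(ifelse(total_tc[key_tc] > 0,
                                               df$n / total_tc[key_tc],
                                               NA_real_))
  out <- df[order(df$cell_type, df$cohort, df$patient),
            c("cell_type", "cohort", "patient", "n", "cohort_share",
              "patient_contribution")]
  rownames(out) <- NULL
  out
}

#' Per-patient IgG/IgA plasma-cell ratio
#'
#' Ratio of IGHG-isotype to IGHA-isotype plasma cells per patient, from the
#' provided isotype labels (isotype assignment is consumed as given, e.g.
#' from IGHG1-high vs IGHA1/JCHAIN-high cluster identities). A patient with
#' IgG cells but no IgA cells gets an `NA` ratio flagged `no_IgA` rather than
#' a pseudocount; the ratios feed plots, not models.
#'
#' @param metadata One row per plasma cell: `patient`, `cohort`, and the
#'   isotype column with values in `{IGHG, IGHA, other}`.
#' @param isotype_column Name of the isotype column.
#' @return Data frame: `patient, cohort, n_IGHG, n_IGHA, ratio, flag`.
#' @export
igg_iga_ratio <- function(metadata, isotype_column = "isotype") {
  .require_cols(metadata, c("patient", "cohort", isotype_column))
  iso <- as.character(metadata[[isotype_column]])
  pat <- unique(data.frame(patient = as.character(metadata$patient),
                           cohort = as.character(metadata$cohort),
                           stringsAsFactors = FALSE))
  count_iso <- function(p, which) {
    sum(metadata$patient == p & iso == which)
  }
  pat$n_IGHG <- vapply(pat$patient, count_iso, 0L, which = "IGHG")
  pat$n_IGHA <- vapply(pat$patient, count_iso, 0L, which = "IGHA")
  pat$ratio <- ifelse(pat$n_IGHA > 0, pat$n_IGHG / pat$n_IGHA, NA_real_)
  pat$flag <- ifelse(pat$n_IGHA > 0, "ok",
                     ifelse(pat$n_IGHG > 0, "no_IgA", "no_plasma"))
  rownames(pat) <- NULL
  pat
}
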