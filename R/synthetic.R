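#' Default marker blocks for the synthetic cell-type taxonomy
#'
#' Eleven mucosal cell types spanning the immune, epithelial and stromal
#' compartments. Each block lists the cell type's own marker genes; during
#' simulation these and the compartment-level marker genes (see
#' [marker_sets()]) are up-lifted by the multiplicative factor `lift` in cells
#' of that type. A lift of 1 produces marker-free null data.
#'
#' @param lift Mean expression multiplier (>= 1) applied to marker genes.
#' @return Named list; each element has `compartment`, `genes`, `lift`.
#' @export
default_marker_blocks <- function(lift = 5) {
  stopifnot(is.numeric(lift), length(lift) == 1L, lift >= 1)
  blocks <- list(
    T_CD8_Trm_activated = list(compartment = "immune",
                               genes = c("GZMB", "CCL4", "IFNG")),
    T_CD8_Trm  = list(compartment = "immune",
                      genes = c("CD8A", "ITGAE", "IL7R")),
    T_CD4      = list(compartment = "immune",
                      genes = c("CD4", "CCR7", "TCF7")),
    B_cell     = list(compartment = "immune",
                      genes = c("MS4A1", "CD19", "BANK1")),
    Plasma_IgA = list(compartment = "immune",
                      genes = c("IGHA1", "IGHA2", "JCHAIN")),
    Plasma_IgG = list(compartment = "immune",
                      genes = c("IGHG1", "IGHG3", "XBP1")),
    Myeloid    = list(compartment = "immune",
                      genes = c("LYZ", "S100A8", "ITGAM")),
    Enterocyte = list(compartment = "epithelial",
                      genes = c("FABP1", "CA2", "GUCA2A")),
    Goblet     = list(compartment = "epithelial",
                      genes = c("MUC2", "TFF3", "ZG16")),
    Fibroblast = list(compartment = "stromal",
                      genes = c("PDGFRA", "LUM", "DCN")),
    Endothelial = list(compartment = "stromal",
                       genes = c("PECAM1", "CLDN5", "RAMP2"))
  )
  lapply(blocks, function(b) c(b, list(lift = lift)))
}

#' Default cohort composition vectors
#'
#' Cell-type proportions per cohort. The MC cohort carries the planted
#' compositional shifts: activated CD8 Trm doubled (0.10 vs 0.05) and IgG
#' plasma cells expanded (0.05 vs 0.02) relative to both control cohorts,
#' compensated in the epithelial fractions so every vector sums to 1.
#'
#' @return Named list of named numeric vectors (one per cohort).
#' @export
default_composition <- function() {
  types <- names(default_marker_blocks())
  ctrl <- c(0.05, 0.12, 0.18, 0.08, 0.10, 0.02, 0.10, 0.15, 0.08, 0.07, 0.05)
  mc   <- c(0.10, 0.12, 0.17, 0.08, 0.09, 0.05, 0.10, 0.11, 0.08, 0.06, 0.04)
  names(ctrl) <- names(mc) <- types
  list(MC = mc, chronic_diarrhea = ctrl, unaffected = ctrl)
}

#' Clonal structure specification for the repertoire generator
#'
#' @param n_clonotypes Clonotypes simulated per patient.
#' @param expansion_prob Probability that a clonotype is expanded (>= 2 cells).
#' @param expanded_extra_mean Poisson mean of cells beyond 2 for expanded
#'   clonotypes.
#' @param share_prob Named per-cohort probability that an expanded clonotype
#'   spans a second cell cluster (the planted cross-cluster sharing rate).
#' @param clusters Cluster label set cells are distributed over.
#' @param tra_prob Probability a clonotype has a productive TRA chain in
#'   addition to its TRB chain.
#' @param nonproductive_frac Fraction of cells receiving an extra
#'   non-productive decoy contig.
#' @param low_confidence_frac Fraction of cells receiving an extra
#'   low-confidence decoy contig.
#' @return A list of class `clonal_spec`.
#' @export
clonal_spec <- function(n_clonotypes = 40,
                        expansion_prob = 0.5,
                        expanded_extra_mean = 1.5,
                        share_prob = c(MC = 0.30, chronic_diarrhea = 0.05,
                                       unaffected = 0.05),
                        clusters = paste0("C", 1:6),
                        tra_prob = 0.8,
                        nonproductive_frac = 0.10,
                        low_confidence_frac = 0.05) {
  probs <- c(share_prob, expansion = expansion_prob,
             tra = tra_prob, np = nonproductive_frac, lc = low_confidence_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("clonal_spec: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_clonotypes >= 1, length(clusters) >= 2L)
  structure(list(n_clonotypes = as.integer(n_clonotypes),
                 expansion_prob = expansion_prob,
                 expanded_extra_mean = expanded_extra_mean,
                 share_prob = share_prob, clusters = clusters,
                 tra_prob = tra_prob,
                 nonproductive_frac = nonproductive_frac,
                 low_confidence_frac = low_confidence_frac),
            class = "clonal_spec")
}

#' Histology count specification
#'
#' Per-probe positive-cell rates per DAPI-stained cell, by cohort. The default
#' plants a rate ratio of 2 for GZMB in MC (0.04 vs 0.02) and a null probe
#' (FOXP3, equal rates). `dispersion` is the gamma-mixing variance: 0 gives
#' pure Poisson counts, > 0 over-dispersed (quasi-Poisson) counts.
#'
#' @param probes Named list: probe -> named per-cohort rate vector.
#' @param n_images_per_cohort Images simulated per cohort.
#' @param dapi_mean Mean DAPI-positive cell count per image.
#' @param dispersion Gamma mixing variance (0 = none).
#' @return A list of class `histology_spec`.
#' @export
histology_spec <- function(probes = list(
                             GZMB = c(MC = 0.04, chronic_diarrhea = 0.02,
                                      unaffected = 0.02),
                             FOXP3 = c(MC = 0.02, chronic_diarrhea = 0.02,
                                       unaffected = 0.02)),
                           n_images_per_cohort = 60,
                           dapi_mean = 500,
                           dispersion = 0) {
  rates <- unlist(probes)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("histology_spec: all probe rates must be positive", call. = FALSE)
  }
  stopifnot(n_images_per_cohort >= 1, dapi_mean > 0, dispersion >= 0)
  structure(list(probes = probes,
                 n_images_per_cohort = as.integer(n_images_per_cohort),
                 dapi_mean = dapi_mean, dispersion = dispersion),
            class = "histology_spec")
}

#' Simulation configuration
#'
#' Bundles every knob of the three synthetic generators. Defaults encode the
#' study conditions the downstream modules are evaluated under: cohorts of
#' 8 / 6 / 5 patients (MC / chronic_diarrhea / unaffected), 2000 cells per
#' patient, marker lift 5, 40 clonotypes per patient with a 30% vs 5% planted
#' sharing excess, and 60 histology images per cohort with a planted rate
#' ratio of 2.
#'
#' @param n_patients Named integer vector: patients per cohort.
#' @param n_cells_per_patient Cells simulated per patient.
#' @param n_genes Total genes (markers + 13 mitochondrial + filler).
#' @param marker_blocks See [default_marker_blocks()].
#' @param composition See [default_composition()]; each vector must sum to 1.
#' @param clonal See [clonal_spec()].
#' @param histology See [histology_spec()].
#' @param mito_fraction_range Per-cell planted mitochondrial UMI fraction is
#'   drawn uniformly from this interval.
#' @param nb_size Negative-binomial size (inverse dispersion) of UMI counts.
#' @param depth_mean,depth_cv Log-normal mean and coefficient of variation of
#'   per-cell total UMI depth.
#' @param seed Master seed; each generator derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = c(MC = 8, chronic_diarrhea = 6,
                                      unaffected = 5),
                       n_cells_per_patient = 2000,
                       n_genes = 1000,
                       marker_blocks = default_marker_blocks(),
                       composition = default_composition(),
                       clonal = clonal_spec(),
                       histology = histology_spec(),
                       mito_fraction_range = c(0.01, 0.10),
                       nb_size = 2,
                       depth_mean = 2500,
                       depth_cv = 0.3,
                       seed = 1L) {
  stopifnot(is.numeric(n_patients), length(n_patients) >= 1L,
            !is.null(names(n_patients)), all(n_patients >= 1),
            n_cells_per_patient >= 1, n_genes >= 1, nb_size > 0,
            depth_mean > 0, depth_cv >= 0)
  if (length(mito_fraction_range) != 2L ||
      any(mito_fraction_range < 0 | mito_fraction_range >= 1) ||
      diff(mito_fraction_range) < 0) {
    stop("mito_fraction_range must be an increasing interval within [0, 1)",
         call. = FALSE)
  }
  types <- names(marker_blocks)
  marker_genes <- unlist(lapply(marker_blocks, `[[`, "genes"),
                         use.names = FALSE)
  if (anyDuplicated(marker_genes)) {
    stop("marker gene names must be unique across blocks", call. = FALSE)
  }
  for (cohort in names(composition)) {
    v <- composition[[cohort]]
    if (abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("composition for cohort '%s' sums to %.6f, not 1",
                   cohort, sum(v)), call. = FALSE)
    }
    if (any(v < 0) || !setequal(names(v), types)) {
      stop(sprintf("composition for cohort '%s' must be a nonnegative vector over the marker-block cell types",
                   cohort), call. = FALSE)
    }
  }
  missing_comp <- setdiff(names(n_patients), names(composition))
  if (length(missing_comp) > 0L) {
    stop(sprintf("no composition vector for cohort(s): %s",
                 paste(missing_comp, collapse = ", ")), call. = FALSE)
  }
  structure(list(n_patients = setNames(as.integer(n_patients),
                                       names(n_patients)),
                 n_cells_per_patient = as.integer(n_cells_per_patient),
                 n_genes = as.integer(n_genes),
                 marker_blocks = marker_blocks, composition = composition,
                 clonal = clonal, histology = histology,
                 mito_fraction_range = mito_fraction_range,
                 nb_size = nb_size, depth_mean = depth_mean,
                 depth_cv = depth_cv, seed = as.integer(seed)),
            class = "sim_config")
}

# The 13 protein-coding mitochondrial genes; the QC prefix rule keys on "MT-".
mito_gene_names <- function() {
  paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
                  "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))
}

.patient_ids <- function(config) {
  unlist(lapply(names(config$n_patients), function(cohort) {
    sprintf("%s_%02d", cohort, seq_len(config$n_patients[[cohort]]))
  }), use.names = FALSE)
}

.patient_cohorts <- function(config) {
  rep(names(config$n_patients), config$n_patients)
}

#' Generate a synthetic cell dataset with planted ground truth
#'
#' Draws UMI counts from a negative binomial with log-normal gene-level base
#' means. Marker genes (cell-type blocks plus their compartment's curated
#' markers) are up-lifted in cells of the matching type; 13 `MT-` genes carry
#' a planted per-cell mitochondrial fraction; cell types are sampled per
#' cohort from the composition vectors. Identical `(config, seed)` yields
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a
#'   [SingleCellExperiment::SingleCellExperiment] with a sparse `counts`
#'   assay and per-cell `patient`, `cohort`, `platform`, `cell_type`,
#'   `compartment` metadata) and `truth` (per-cell planted labels plus the
#'   marker map).
#' @export
generate_cell_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 1L))

  blocks <- config$marker_blocks
  comp_sets <- marker_sets()
  marker_genes <- unique(c(unlist(lapply(blocks, `[[`, "genes"),
                                  use.names = FALSE),
                           unlist(comp_sets, use.names = FALSE)))
  mito <- mito_gene_names()
  n_named <- length(marker_genes) + length(mito)
  if (config$n_genes < n_named + 10L) {
    stop(sprintf("n_genes = %d is too small for %d marker + mitochondrial genes",
                 config$n_genes, n_named), call. = FALSE)
  }
  filler <- sprintf("GENE%04d", seq_len(config$n_genes - n_named))
  genes <- c(marker_genes, mito, filler)
  is_mito <- genes %in% mito

  base_mean <- rlnorm(length(genes), meanlog = log(0.1), sdlog = 1)
  mito_weight <- rlnorm(length(mito), meanlog = 0, sdlog = 0.5)
  mito_weight <- mito_weight / sum(mito_weight)

  # per cell type: multiplicative lift pattern over genes
  lift_of <- lapply(blocks, function(b) {
    lifted <- c(b$genes, comp_sets[[b$compartment]])
    ifelse(genes %in% lifted, b$lift, 1)
  })

  patients <- .patient_ids(config)
  cohorts <- .patient_cohorts(config)
  n_per <- config$n_cells_per_patient
  mats <- vector("list", length(patients))
  meta <- vector("list", length(patients))

  for (p in seq_along(patients)) {
    cohort <- cohorts[[p]]
    comp <- config$composition[[cohort]]
    cell_types <- sample(names(comp), n_per, replace = TRUE, prob = comp)
    f <- runif(n_per, config$mito_fraction_range[1],
               config$mito_fraction_range[2])
    depth <- rlnorm(n_per, meanlog = log(config$depth_mean), sdlog = config$depth_cv)

    mu <- matrix(0, nrow = length(genes), ncol = n_per)
    for (j in seq_len(n_per)) {
      m <- base_mean * lift_of[[cell_types[j]]]
      m[is_mito] <- 0
      m[is_mito] <- mito_weight * (f[j] / (1 - f[j])) * sum(m)
      mu[, j] <- m / sum(m) * depth[j]
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_size),
                     nrow = length(genes))
    rownames(counts) <- genes
    colnames(counts) <- sprintf("%s_C%05d", patients[p], seq_len(n_per))
    mats[[p]] <- .sparse(counts)
    meta[[p]] <- data.frame(
      barcode = colnames(counts), patient = patients[p], cohort = cohort,
      platform = if (p %% 2L == 1L) "tenx" else "indrops",
      cell_type = cell_types,
      compartment = vapply(blocks[cell_types], `[[`, "", "compartment"),
      stringsAsFactors = FALSE, row.names = NULL)
  }

  counts <- do.call(cbind, mats)
  cells <- do.call(rbind, meta)
  rownames(cells) <- cells$barcode
  dataset <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cells))
  truth <- list(cells = cells,
                marker_blocks = blocks,
                composition = config$composition,
                seed = config$seed)
  list(dataset = dataset, truth = truth)
}

# Random CDR3 amino-acid sequence, C...F, unique against `registry`.
.new_cdr3 <- function(registry) {
  aa <- c("A","R","N","D","E","Q","G","H","I","L","K","M","F","P","S","T",
          "W","Y","V")
  repeat {
    len <- sample(6:18, 1L)
    s <- paste0("C", paste(sample(aa, len, replace = TRUE), collapse = ""), "F")
    if (is.null(registry[[s]])) {
      registry[[s]] <- TRUE
      return(s)
    }
  }
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic per-patient TCR contig tables with planted truth
#'
#' Emits one filtered-contig table per patient in the 10X dialect (columns
#' `barcode, is_cell, high_confidence, chain, v_gene, j_gene, cdr3, cdr3_nt,
#' productive, raw_clonotype_id`, plus a `library_id` column). Planted
#' expanded clonotypes have >= 2 cells; planted shared clonotypes span two
#' cell clusters at the cohort-specific rate `clonal$share_prob` (the planted
#' sharing excess). A configurable fraction of non-productive and
#' low-confidence decoy contigs exercises the filtering rules. Each patient's
#' cells are split across two libraries so CDR3-set merging is exercised.
#'
#' @param config A [sim_config()] with a `clonal` spec.
#' @return List with `contigs` (named list of per-patient data frames),
#'   `cell_clusters` (barcode -> planted cluster table) and `truth`
#'   (per-clonotype size, expansion and sharing flags).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$clonal
  if (is.null(cl)) stop("config has no clonal spec", call. = FALSE)
  bad <- cl$share_prob < 0 | cl$share_prob > 1
  if (any(bad)) {
    stop("sharing probability outside [0, 1] for cohort(s): ",
         paste(names(cl$share_prob)[bad], collapse = ", "), call. = FALSE)
  }
  set.seed(.derive_seed(config$seed, 2L))

  registry <- new.env(parent = emptyenv())
  patients <- .patient_ids(config)
  cohorts <- .patient_cohorts(config)
  contigs <- setNames(vector("list", length(patients)), patients)
  truth_list <- vector("list", length(patients))
  cluster_list <- vector("list", length(patients))

  for (p in seq_along(patients)) {
    patient <- patients[p]
    cohort <- cohorts[p]
    K <- cl$n_clonotypes

    trb <- vapply(seq_len(K), function(k) .new_cdr3(registry), "")
    has_tra <- runif(K) < cl$tra_prob
    tra <- rep(NA_character_, K)
    tra[has_tra] <- vapply(seq_len(sum(has_tra)),
                           function(i) .new_cdr3(registry), "")
    expanded <- runif(K) < cl$expansion_prob
    size <- ifelse(expanded, 2L + rpois(K, cl$expanded_extra_mean), 1L)
    home <- sample(cl$clusters, K, replace = TRUE)
    p_share <- unname(cl$share_prob[cohort])
    if (is.na(p_share)) {
      stop(sprintf("clonal_spec$share_prob has no entry for cohort '%s'",
                   cohort), call. = FALSE)
    }
    shared <- size >= 2L & runif(K) < p_share
    second <- rep(NA_character_, K)
    for (k in which(shared)) {
      second[k] <- sample(setdiff(cl$clusters, home[k]), 1L)
    }
    vb <- sprintf("TRBV%d", sample(30L, K, replace = TRUE))
    jb <- sprintf("TRBJ%d", sample(2L, K, replace = TRUE))
    va <- sprintf("TRAV%d", sample(40L, K, replace = TRUE))
    ja <- sprintf("TRAJ%d", sample(50L, K, replace = TRUE))

    # per-cell layout: shared clonotypes put their first cell in the home
    # cluster, the second in the partner cluster, the rest in either
    clono <- rep(seq_len(K), size)
    pos <- sequence(size)
    n_cells <- length(clono)
    cell_cluster <- home[clono]
    extra <- which(shared[clono] & pos > 2L)
    cell_cluster[shared[clono] & pos == 2L] <- second[clono[shared[clono] &
                                                              pos == 2L]]
    if (length(extra) > 0L) {
      pick <- runif(length(extra)) < 0.5
      cell_cluster[extra][pick] <- second[clono[extra][pick]]
    }
    barcode <- sprintf("%s_T%05d", patient, seq_len(n_cells))
    lib <- sprintf("%s_lib%d", patient, (seq_len(n_cells) %% 2L) + 1L)
    clono_id <- sprintf("clonotype%d", clono)

    contig_of <- function(bc, chain, vg, jg, cdr3, productive, high_conf,
                          clid, lb) {
      data.frame(barcode = bc, is_cell = "true",
                 high_confidence = high_conf, chain = chain,
                 v_gene = vg, j_gene = jg, cdr3 = cdr3,
                 cdr3_nt = vapply(nchar(cdr3) * 3L, .random_nt, ""),
                 productive = productive, raw_clonotype_id = clid,
                 library_id = lb, stringsAsFactors = FALSE)
    }
    parts <- list(contig_of(barcode, "TRB", vb[clono], jb[clono], trb[clono],
                            "true", "true", clono_id, lib))
    with_tra <- which(has_tra[clono])
    if (length(with_tra) > 0L) {
      i <- with_tra
      parts[[2L]] <- contig_of(barcode[i], "TRA", va[clono[i]], ja[clono[i]],
                               tra[clono[i]], "true", "true", clono_id[i],
                               lib[i])
    }
    np <- which(runif(n_cells) < cl$nonproductive_frac)
    if (length(np) > 0L) {
      decoys <- vapply(seq_along(np), function(i) .new_cdr3(registry), "")
      parts[[length(parts) + 1L]] <-
        contig_of(barcode[np], "TRA", va[clono[np]], ja[clono[np]], decoys,
                  "false", "true", clono_id[np], lib[np])
    }
    lc <- which(runif(n_cells) < cl$low_confidence_frac)
    if (length(lc) > 0L) {
      decoys <- vapply(seq_along(lc), function(i) .new_cdr3(registry), "")
      parts[[length(parts) + 1L]] <-
        contig_of(barcode[lc], "TRB", vb[clono[lc]], jb[clono[lc]], decoys,
                  "true", "false", clono_id[lc], lib[lc])
    }
    contigs[[patient]] <- do.call(rbind, parts)

    cluster_list[[p]] <- data.frame(barcode = barcode, patient = patient,
                                    cohort = cohort, cluster = cell_cluster,
                                    stringsAsFactors = FALSE)
    key <- vapply(seq_len(K), function(k) {
      paste(sort(c(trb[k], tra[k][!is.na(tra[k])])), collapse = ";")
    }, "")
    truth_list[[p]] <- data.frame(patient = patient, cohort = cohort,
                                  cdr3_key = key, n_cells = size,
                                  expanded = size >= 2L, shared = shared,
                                  home_cluster = home,
                                  stringsAsFactors = FALSE)
  }
  list(contigs = contigs,
       cell_clusters = do.call(rbind, cluster_list),
       truth = list(clonotypes = do.call(rbind, truth_list),
                    clusters = cl$clusters, share_prob = cl$share_prob,
                    seed = config$seed))
}

#' Merge a generated repertoire bundle into per-patient repertoires
#'
#' Convenience bridge from [generate_repertoire()] to the TCR module: runs
#' [merge_clonotypes()] on every patient's contig table with the planted
#' cluster labels attached.
#'
#' @param rep_out The list returned by [generate_repertoire()].
#' @return List of `repertoire` objects, one per patient.
#' @export
merge_generated_repertoires <- function(rep_out) {
  cluster_map <- setNames(rep_out$cell_clusters$cluster,
                          rep_out$cell_clusters$barcode)
  lapply(names(rep_out$contigs), function(patient) {
    cohort <- rep_out$cell_clusters$cohort[
      match(patient, rep_out$cell_clusters$patient)]
    merge_clonotypes(rep_out$contigs[[patient]], patient, cohort, cluster_map)
  })
}

#' Generate synthetic histology counts with planted rate ratios
#'
#' Per image: a DAPI-positive cell total drawn Poisson around
#' `histology$dapi_mean`, and per probe a positive-cell count drawn
#' `Poisson(rate x DAPI)`, optionally over-dispersed by gamma mixing
#' (`histology$dispersion` > 0). Truth stores the log rate ratio of every
#' cohort against the MC reference.
#'
#' @param config A [sim_config()] with a `histology` spec.
#' @return List with `counts` (data frame: `image_id, patient, cohort, probe,
#'   compartment, count, dapi_total`) and `truth` (per-probe log rate ratios
#'   vs MC).
#' @export
generate_histology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hs <- config$histology
  if (is.null(hs)) stop("config has no histology spec", call. = FALSE)
  rates <- unlist(hs$probes)
  if (any(rates <= 0)) stop("nonpositive probe rate", call. = FALSE)
  set.seed(.derive_seed(config$seed, 3L))

  rows <- list()
  n_img <- hs$n_images_per_cohort
  for (cohort in names(config$n_patients)) {
    pats <- sprintf("%s_%02d", cohort, seq_len(config$n_patients[[cohort]]))
    dapi <- pmax(1L, rpois(n_img, hs$dapi_mean))
    for (probe in names(hs$probes)) {
      rate <- hs$probes[[probe]][[cohort]]
      g <- if (hs$dispersion > 0) {
        rgamma(n_img, shape = 1 / hs$dispersion, scale = hs$dispersion)
      } else {
        rep(1, n_img)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = sprintf("%s_img%03d", cohort, seq_len(n_img)),
        patient = pats[((seq_len(n_img) - 1L) %% length(pats)) + 1L],
        cohort = cohort, probe = probe, compartment = "lamina_propria",
        count = pmin(rpois(n_img, rate * g * dapi), dapi),
        dapi_total = dapi, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, lapply(names(hs$probes), function(probe) {
    r <- hs$probes[[probe]]
    data.frame(probe = probe, cohort = names(r),
               true_log_rr = log(unname(r)) - log(unname(r[["MC"]])),
               stringsAsFactors = FALSE)
  }))
  list(counts = do.call(rbind, rows),
       truth = list(log_rate_ratios = truth, dispersion = hs$dispersion,
                    seed = config$seed))
}
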