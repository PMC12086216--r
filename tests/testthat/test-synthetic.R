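test_that("all three generators are byte-identical under a fixed seed", {
  cfg <- small_config(seed = 7, n_cells = 60)
  expect_identical(generate_cell_dataset(cfg)$dataset |>
                     SummarizedExperiment::assay() |> as.matrix(),
                   generate_cell_dataset(cfg)$dataset |>
                     SummarizedExperiment::assay() |> as.matrix())
  expect_identical(generate_repertoire(cfg), generate_repertoire(cfg))
  expect_identical(generate_histology(cfg), generate_histology(cfg))
})

test_that("generator streams are independent: one call never perturbs another", {
  cfg <- small_config(seed = 19, n_cells = 40)
  r_alone <- generate_repertoire(cfg)
  invisible(generate_cell_dataset(cfg))
  r_after <- generate_repertoire(cfg)
  expect_identical(r_alone, r_after)
})

test_that("metadata, matrix and truth stay aligned", {
  cfg <- small_config(seed = 2, n_cells = 50)
  g <- generate_cell_dataset(cfg)
  meta <- as.data.frame(SummarizedExperiment::colData(g$dataset))
  expect_equal(nrow(meta), ncol(g$dataset))
  expect_identical(meta$barcode, colnames(g$dataset))
  expect_identical(g$truth$cells$barcode, meta$barcode)
  expect_identical(g$truth$cells$compartment, meta$compartment)
  expect_equal(nrow(meta), 6L * 50L)
  # mitochondrial genes exist and carry the planted fraction range loosely
  counts <- SummarizedExperiment::assay(g$dataset)
  mito <- startsWith(rownames(counts), "MT-")
  expect_equal(sum(mito), 13L)
  frac <- Matrix::colSums(counts[mito, ]) / Matrix::colSums(counts)
  expect_true(mean(frac) > 0.005 && mean(frac) < 0.15)
})

test_that("every contig barcode belongs to exactly one patient table", {
  cfg <- small_config(seed = 3)
  r <- generate_repertoire(cfg)
  per_patient <- lapply(r$contigs, function(d) unique(d$barcode))
  all_bc <- unlist(per_patient, use.names = FALSE)
  expect_false(any(duplicated(all_bc)))
  expect_setequal(all_bc, r$cell_clusters$barcode)
})

test_that("invalid configurations fail with informative errors", {
  bad_comp <- default_composition()
  bad_comp$MC[1] <- bad_comp$MC[1] + 0.1
  expect_error(small_config(composition = bad_comp), "MC")
  expect_error(clonal_spec(share_prob = c(MC = 1.3, chronic_diarrhea = 0,
                                          unaffected = 0)),
               "\\[0, 1\\]")
  expect_error(histology_spec(probes = list(G = c(MC = -1,
                                                  chronic_diarrhea = 1,
                                                  unaffected = 1))),
               "positive")
  expect_error(small_config(mito_fraction_range = c(0.5, 0.1)), "interval")
})

test_that("planted composition shifts appear in per-patient proportions", {
  # MC doubles the activated CD8 Trm fraction relative to controls
  diff_sign <- vapply(1:8, function(s) {
    g <- generate_cell_dataset(small_config(seed = 400 + s, n_cells = 500))
    tab <- per_patient_proportions(g$truth$cells,
                                   denominator_scope = "all_immune")
    sub <- tab[tab$cell_type == "T_CD8_Trm_activated", ]
    mean(sub$proportion[sub$cohort == "MC"]) >
      mean(sub$proportion[sub$cohort != "MC"])
  }, TRUE)
  expect_true(all(diff_sign))
})

test_that("an all-singleton expansion distribution yields no expanded clonotypes", {
  cfg <- small_config(seed = 5, clonal = clonal_spec(expansion_prob = 0))
  reps <- merge_generated(generate_repertoire(cfg))
  expect_true(all(vapply(reps, function(r) length(classify_expanded(r)), 0L)
                  == 0L))
})

test_that("zero sharing probability empties the off-diagonal", {
  cfg <- small_config(seed = 6,
                      clonal = clonal_spec(share_prob = c(
                        MC = 0, chronic_diarrhea = 0, unaffected = 0)))
  reps <- merge_generated(generate_repertoire(cfg))
  m <- sharing_matrix(reps)
  expect_true(all(m[upper.tri(m)] == 0))
})

test_that("repertoire truth matches what the tcr module reconstructs", {
  cfg <- small_config(seed = 8)
  r <- generate_repertoire(cfg)
  reps <- merge_generated(r)
  for (rep in reps[1:2]) {
    truth <- r$truth$clonotypes[r$truth$clonotypes$patient == rep$patient, ]
    expect_setequal(rep$clonotypes$cdr3_key, truth$cdr3_key)
    merged_sizes <- setNames(rep$clonotypes$n_cells, rep$clonotypes$cdr3_key)
    expect_equal(unname(merged_sizes[truth$cdr3_key]), truth$n_cells)
    expect_setequal(classify_expanded(rep),
                    rep$clonotypes$clonotype_id[rep$clonotypes$cdr3_key %in%
                                                  truth$cdr3_key[truth$expanded]])
  }
})

test_that("equal DAPI totals make offset and no-offset rate ratios agree", {
  records <- data.frame(
    cohort = rep(c("MC", "unaffected"), each = 5),
    count = c(12, 9, 11, 10, 8, 22, 25, 19, 21, 23),
    dapi_total = 250)
  with_off <- poisson_fit(records, use_offset = TRUE)
  without <- poisson_fit(records, use_offset = FALSE)
  expect_equal(with_off$coefficients$rate_ratio[-1],
               without$coefficients$rate_ratio[-1], tolerance = 1e-8)
})

test_that("histology truth records log rate ratios against the MC reference", {
  cfg <- small_config(seed = 10)
  h <- generate_histology(cfg)
  lr <- h$truth$log_rate_ratios
  expect_equal(lr$true_log_rr[lr$probe == "GZMB" & lr$cohort == "MC"], 0)
  expect_equal(lr$true_log_rr[lr$probe == "GZMB" &
                                lr$cohort == "unaffected"], log(0.5))
  expect_true(all(h$counts$count <= h$counts$dapi_total))
})

test_that("datasets round-trip through the Matrix-Market writer", {
  cfg <- small_config(seed = 4, n_cells = 30, n_genes = 300)
  g <- generate_cell_dataset(cfg)
  dir <- withr::local_tempdir()
  write_cell_dataset(g$dataset, dir)
  back <- read_cell_dataset(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back)),
               as.matrix(SummarizedExperiment::assay(g$dataset)))
  expect_equal(
    as.data.frame(SummarizedExperiment::colData(back))$cell_type,
    as.data.frame(SummarizedExperiment::colData(g$dataset))$cell_type)

  write_contigs(generate_repertoire(cfg)$contigs, dir)
  files <- list.files(dir, pattern = "filtered_contig")
  expect_equal(length(files), 6L)
  contigs <- read_contigs(file.path(dir, files[1]))
  expect_true(all(c("barcode", "chain", "cdr3") %in% names(contigs)))
})
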