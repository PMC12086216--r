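contig_row <- function(barcode, chain, cdr3, productive = "true",
                       high_confidence = "true") {
  data.frame(barcode = barcode, chain = chain, cdr3 = cdr3,
             productive = productive, high_confidence = high_confidence,
             stringsAsFactors = FALSE)
}

test_that("identical CDR3 sets merge across libraries into one clonotype", {
  # 3 cells in library 1 and 2 in library 2, all with the same CDR3 pair
  rows <- do.call(rbind, lapply(sprintf("bc%d", 1:5), function(bc) {
    rbind(contig_row(bc, "TRB", "CASSLGQETQYF"),
          contig_row(bc, "TRA", "CAVRDNYGQNFVF"))
  }))
  rep <- merge_clonotypes(rows, "P1")
  expect_equal(nrow(rep$clonotypes), 1L)
  expect_equal(rep$clonotypes$n_cells, 5L)
  expect_equal(rep$clonotypes$cdr3_key,
               paste(sort(c("CASSLGQETQYF", "CAVRDNYGQNFVF")), collapse = ";"))
})

test_that("non-productive and low-confidence contigs are excluded from CDR3 sets", {
  rows <- rbind(
    contig_row("bc1", "TRB", "CASSAAAF"),
    contig_row("bc1", "TRA", "CAVDECOYF", productive = "false"),
    contig_row("bc2", "TRB", "CASSAAAF"),
    contig_row("bc2", "TRA", "CAVOTHERF", high_confidence = "false"))
  rep <- merge_clonotypes(rows, "P1")
  # both barcodes reduce to the same productive TRB -> one clonotype
  expect_equal(nrow(rep$clonotypes), 1L)
  expect_equal(rep$clonotypes$cdr3_key, "CASSAAAF")
  expect_equal(rep$clonotypes$n_cells, 2L)
})

test_that("disjoint CDR3 sets stay separate and duplicates warn", {
  rows <- rbind(contig_row("bc1", "TRB", "CASSXF"),
                contig_row("bc2", "TRB", "CASSYF"))
  rep <- merge_clonotypes(rows, "P1")
  expect_equal(nrow(rep$clonotypes), 2L)
  expect_warning(rep2 <- merge_clonotypes(rbind(rows, rows), "P1"),
                 "duplicate")
  expect_equal(rep2$clonotypes[order(rep2$clonotypes$cdr3_key), ],
               rep$clonotypes[order(rep$clonotypes$cdr3_key), ])
})

test_that("clonotype frequencies are proportions of clonotype-bearing cells", {
  rows <- rbind(contig_row("bc1", "TRB", "CASSXF"),
                contig_row("bc2", "TRB", "CASSXF"),
                contig_row("bc3", "TRB", "CASSYF"),
                contig_row("bc4", "TRB", "CASSZF"))
  freq <- clonotype_frequencies(merge_clonotypes(rows, "P1"))
  expect_equal(freq$proportion, c(0.5, 0.25, 0.25))
  expect_equal(sum(freq$proportion), 1)
  one <- clonotype_frequencies(
    merge_clonotypes(contig_row("bc1", "TRB", "CASSXF"), "P1"))
  expect_equal(one$proportion, 1)
})

test_that("Shannon diversity matches closed forms and the vegan implementation", {
  expect_equal(shannon_diversity(5), 0)
  expect_equal(shannon_diversity(rep(3, 7)), log(7))
  expect_equal(shannon_diversity(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_diversity(c(2, 1, 1)),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:20, sample(2:10, 1))
    expect_equal(shannon_diversity(x),
                 unname(vegan::diversity(x, index = "shannon")))
  }
  expect_error(shannon_diversity(numeric(0)), "nonempty")
})

test_that("diversity is relabeling-invariant and grows when a singleton splits off", {
  x <- c(9, 4, 2)
  expect_equal(shannon_diversity(x), shannon_diversity(rev(x)))
  for (i in 1:5) {
    moved <- c(x[1] - 1, x[-1], 1)
    expect_gt(shannon_diversity(moved), shannon_diversity(x))
    x <- moved
  }
})

test_that("expansion requires at least 2 cells", {
  rows <- rbind(contig_row("bc1", "TRB", "CASSXF"),
                contig_row("bc2", "TRB", "CASSXF"),
                contig_row("bc3", "TRB", "CASSYF"))
  rep <- merge_clonotypes(rows, "P1")
  expanded <- classify_expanded(rep)
  expect_equal(length(expanded), 1L)
  expect_equal(rep$clonotypes$n_cells[rep$clonotypes$clonotype_id == expanded],
               2L)
  empty <- merge_clonotypes(contig_row("bc9", "TRB", "CASSQF",
                                       productive = "false"), "P2")
  expect_equal(classify_expanded(empty), character(0))
})

test_that("sharing matrix counts spanning clonotypes off-diagonal and totals on it", {
  rep <- toy_repertoire("P1", "MC",
                        sizes = c(2, 2, 1, 1, 1, 1, 1),
                        clusters = list(c("A", "B"), "A", "A", "A", "A", "A",
                                        "B"))
  m <- sharing_matrix(list(rep), clusters = c("A", "B"))
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(m["A", "A"], 6L)  # six distinct clonotypes touch cluster A
  expect_equal(m["B", "B"], 2L)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) >= apply(m - diag(diag(m)), 1, max)))

  confined <- toy_repertoire("P2", "MC", sizes = c(2, 3),
                             clusters = list("A", "B"))
  m2 <- sharing_matrix(list(confined), clusters = c("A", "B"))
  expect_equal(m2["A", "B"], 0L)
})

test_that("unexpanded clonotypes never contribute to off-diagonal sharing", {
  cfg <- small_config(seed = 9,
                      clonal = clonal_spec(expansion_prob = 0,
                                           share_prob = c(
                                             MC = 0.5,
                                             chronic_diarrhea = 0.5,
                                             unaffected = 0.5)))
  reps <- merge_generated(generate_repertoire(cfg))
  m <- sharing_matrix(reps)
  expect_true(all(m[upper.tri(m)] == 0))
  expect_true(all(vapply(reps, function(r) length(classify_expanded(r)),
                         0L) == 0L))
})

test_that("Fisher 2x2 matches enumeration on the worked example and edge cases", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-7)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 2, 0), 2)), 1)
  # row/column exchange symmetry
  t1 <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(fisher_exact_2x2(t1), fisher_exact_2x2(t(t1)))
  expect_equal(fisher_exact_2x2(t1), fisher_exact_2x2(t1[2:1, ]))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("sharing test flags only clusters significant in both comparisons", {
  # cluster X: strong MC excess vs chronic, none vs unaffected
  mk <- function(patient, cohort, n_shared, n_unique) {
    sizes <- rep(2, n_shared + n_unique)
    clusters <- c(rep(list(c("X", "Y")), n_shared), rep(list("X"), n_unique))
    toy_repertoire(patient, cohort, sizes, clusters)
  }
  reps <- list(mk("M1", "MC", 20, 5),
               mk("C1", "chronic_diarrhea", 1, 24),
               mk("U1", "unaffected", 18, 6))
  res <- sharing_test(reps, clusters = c("X", "Y"))
  tx <- res$tests[res$tests$cluster == "X", ]
  expect_lt(tx$p_adj[tx$comparison == "chronic_diarrhea"], 0.05)
  expect_gt(tx$p_adj[tx$comparison == "unaffected"], 0.05)
  expect_false(res$flags$dual_significant[res$flags$cluster == "X"])
})

test_that("sharing test contingency counts decompose expanded clonotypes", {
  cfg <- small_config(seed = 12)
  reps <- merge_generated(generate_repertoire(cfg))
  res <- sharing_test(reps)
  # shared + unique equals expanded clonotypes observed in the cluster
  occ <- mcatlas:::.clonotype_occupancy(reps)
  occ <- occ[occ$expanded, ]
  for (i in sample(nrow(res$tests), 4)) {
    row <- res$tests[i, ]
    in_cluster <- vapply(occ$clusters, function(cl) row$cluster %in% cl, TRUE)
    mc <- occ$cohort == "MC" & in_cluster
    expect_equal(row$ref_shared + row$ref_unique, sum(mc))
    expect_equal(row$ref_shared, sum(mc & occ$n_clusters >= 2))
  }
})

test_that("clusters absent from a cohort are not testable and skip the BH family", {
  reps <- list(toy_repertoire("M1", "MC", c(2, 2), list("A", c("A", "B"))),
               toy_repertoire("C1", "chronic_diarrhea", 2, list("A")),
               toy_repertoire("U1", "unaffected", 2, list("A")))
  res <- sharing_test(reps, clusters = c("A", "B"))
  b <- res$tests[res$tests$cluster == "B", ]
  expect_true(all(!b$testable))
  expect_true(all(is.na(b$p_adj)))
  expect_false(res$flags$dual_significant[res$flags$cluster == "B"])
})
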