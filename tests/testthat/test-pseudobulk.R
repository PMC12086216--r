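pb_fixture <- function() {
  # P1/typeA: 5 cells, P1/typeB: 4 cells (dropped), P2/typeA: 6 cells
  counts <- cbind(
    matrix(1:10, nrow = 2, ncol = 5),      # P1 typeA
    matrix(1, nrow = 2, ncol = 4),         # P1 typeB
    matrix(2, nrow = 2, ncol = 6))         # P2 typeA
  rownames(counts) <- c("g1", "g2")
  meta <- data.frame(
    patient = c(rep("P1", 9), rep("P2", 6)),
    cohort = c(rep("MC", 9), rep("unaffected", 6)),
    cell_type = c(rep("typeA", 5), rep("typeB", 4), rep("typeA", 6)),
    stringsAsFactors = FALSE)
  make_sce(counts, meta)
}

test_that("aggregation sums raw counts per group and applies the 5-cell floor", {
  pb <- pb_aggregate(pb_fixture(), min_cells = 5)
  expect_setequal(colnames(pb$counts), c("P1|typeA", "P2|typeA"))
  expect_false("P1|typeB" %in% pb$groups$group)   # 4-cell group dropped
  expect_equal(unname(pb$counts[, "P1|typeA"]), c(1 + 3 + 5 + 7 + 9,
                                                  2 + 4 + 6 + 8 + 10))
  expect_equal(pb$groups$n_cells[pb$groups$group == "P2|typeA"], 6L)
  expect_true(is.integer(pb$counts))
})

test_that("two-cell summation example and exact conservation hold", {
  counts <- matrix(c(1, 2, 3, 4), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  meta <- data.frame(patient = "P1", cohort = "MC", cell_type = "t",
                     stringsAsFactors = FALSE)[c(1, 1), ]
  pb <- pb_aggregate(make_sce(counts, meta), min_cells = 2)
  expect_equal(unname(pb$counts[, 1]), c(4, 6))

  cfg <- small_config(seed = 17, n_cells = 60, n_genes = 300)
  sce <- generate_cell_dataset(cfg)$dataset
  pb2 <- pb_aggregate(sce, min_cells = 5)
  kept <- .subset2(pb2$groups, "group")
  meta2 <- as.data.frame(SummarizedExperiment::colData(sce))
  cell_group <- paste(meta2$patient, meta2$cell_type, sep = "|")
  kept_cells <- cell_group %in% kept
  expect_identical(sum(pb2$counts),
                   as.integer(sum(SummarizedExperiment::assay(sce)[,
                                                                   kept_cells])))
})

test_that("aggregation with no surviving group is an error", {
  counts <- matrix(1, nrow = 2, ncol = 3,
                   dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  meta <- data.frame(patient = c("P1", "P2", "P3"), cohort = "MC",
                     cell_type = "t", stringsAsFactors = FALSE)
  expect_error(pb_aggregate(make_sce(counts, meta), min_cells = 5),
               "at least 5 cells")
})

test_that("cpm_log scales columns to a million and is depth-invariant", {
  m <- matrix(c(1, 0), nrow = 2, dimnames = list(c("g1", "g2"), "grp"))
  lcpm <- cpm_log(m)
  expect_equal(unname(lcpm[, 1]), c(log2(1e6 + 1), 0))
  m2 <- cbind(a = c(10, 30), b = c(20, 60))
  rownames(m2) <- c("g1", "g2")
  lcpm2 <- cpm_log(m2)
  expect_equal(lcpm2[, "a"], lcpm2[, "b"])
  expect_error(cpm_log(cbind(z = c(0, 0))), "zero-sum")
})

test_that("rank-sum test is exact without ties and symmetric", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)  # 2/20 orderings as extreme, enumerated
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p, 0.1)
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5))$p, 1)
  expect_true(rank_sum_test(c(5, 5, 5), c(5, 5))$degenerate)
})

test_that("BH adjustment matches the hand-executed step-up example", {
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03)), c(0.015, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment equals the independent step-up oracle on random vectors", {
  set.seed(23)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_step_up(p))
  }
})

de_fixture <- function(seed = 1, n_genes = 60, fold = 4, de_gene = "g001") {
  set.seed(seed)
  patients <- c(sprintf("M%d", 1:4), sprintf("U%d", 1:4))
  cohorts <- rep(c("MC", "unaffected"), each = 4)
  mats <- list()
  meta <- list()
  for (i in seq_along(patients)) {
    mu <- rep(2, n_genes)
    if (cohorts[i] == "MC") mu[1] <- mu[1] * fold
    m <- matrix(rnbinom(n_genes * 20, mu = mu, size = 5), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
    colnames(m) <- sprintf("%s_c%02d", patients[i], 1:20)
    mats[[i]] <- m
    meta[[i]] <- data.frame(patient = patients[i], cohort = cohorts[i],
                            cell_type = "typeA", stringsAsFactors = FALSE)[
                              rep(1, 20), ]
  }
  make_sce(do.call(cbind, mats), do.call(rbind, meta))
}

test_that("cohort_de recovers a planted fold change and flags degenerate genes", {
  sce <- de_fixture(seed = 31)
  pb <- pb_aggregate(sce)
  de <- cohort_de(pb, "typeA", c("MC", "unaffected"))
  expect_equal(nrow(de), 60L)
  top <- de[de$gene == "g001", ]
  expect_gt(top$log2fc, 1)
  expect_lt(top$p, 0.05)
  expect_true(all(de$p_adj >= de$p - 1e-12))
  expect_true(all(de$p_adj <= 1))
})

test_that("an all-zero gene yields log2fc 0 and p 1", {
  sce <- de_fixture(seed = 32)
  counts <- as.matrix(SummarizedExperiment::assay(sce))
  counts["g060", ] <- 0
  sce0 <- make_sce(counts, as.data.frame(SummarizedExperiment::colData(sce)))
  de <- cohort_de(pb_aggregate(sce0), "typeA", c("MC", "unaffected"))
  zero <- de[de$gene == "g060", ]
  expect_equal(zero$log2fc, 0)
  expect_equal(zero$p, 1)
})

test_that("cohort_de requires two patients per side", {
  sce <- de_fixture(seed = 33)
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  keep <- meta$patient != "U1" & meta$patient != "U2" & meta$patient != "U3"
  sce1 <- sce[, keep]
  expect_error(cohort_de(pb_aggregate(sce1), "typeA", c("MC", "unaffected")),
               "fewer than 2")
})

test_that("results are invariant to permuting patient columns within cohorts", {
  sce <- de_fixture(seed = 34)
  pb <- pb_aggregate(sce)
  de1 <- cohort_de(pb, "typeA", c("MC", "unaffected"))
  perm <- c("M3|typeA", "M1|typeA", "M4|typeA", "M2|typeA",
            "U2|typeA", "U4|typeA", "U1|typeA", "U3|typeA")
  pb2 <- pb
  pb2$counts <- pb$counts[, perm]
  pb2$groups <- pb$groups[match(perm, pb$groups$group), ]
  de2 <- cohort_de(pb2, "typeA", c("MC", "unaffected"))
  expect_equal(de1$p, de2$p)
  expect_equal(de1$log2fc, de2$log2fc)
})

test_that("cluster_markers ranks a planted marker first", {
  set.seed(41)
  n <- 40
  counts <- matrix(rpois(20 * 2 * n, 1), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
  counts[1, 1:n] <- counts[1, 1:n] + 20
  colnames(counts) <- sprintf("c%03d", seq_len(2 * n))
  labels <- setNames(rep(c("hot", "bg"), each = n), colnames(counts))
  mk <- cluster_markers(normalize_log(counts), labels, "hot")
  expect_equal(mk$gene[1], "g01")
  expect_true(mk$candidate[1])
})
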