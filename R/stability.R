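#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index computed from the pair-counting
#' contingency table. Inputs may be plain vectors of equal length or vectors
#' named by cell barcode, in which case the comparison is restricted to the
#' common barcodes (as needed when one labeling comes from a subsample).
#' Returns 1 for identical partitions and is invariant to label renaming.
#'
#' @param labels_a,labels_b Cluster labels (any atomic type), optionally
#'   named by barcode; `cluster_labeling` objects are accepted.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  a <- if (inherits(labels_a, "cluster_labeling")) labels_a$labels else labels_a
  b <- if (inherits(labels_b, "cluster_labeling")) labels_b$labels else labels_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) < 2L) {
      stop("fewer than 2 barcodes common to both labelings", call. = FALSE)
    }
    a <- a[common]
    b <- b[common]
  } else if (length(a) != length(b)) {
    stop("unnamed labelings must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 elements", call. = FALSE)

  fa <- match(a, unique(a))
  fb <- match(b, unique(b))
  ka <- max(fa)
  kb <- max(fb)
  n <- length(a)
  tab <- tabulate((fa - 1L) * kb + fb, ka * kb)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(tabulate(fa, ka)))
  sum_b <- sum(ch2(tabulate(fb, kb)))
  total <- ch2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Graph-based clustering backend (PCA -> SNN -> modularity)
#'
#' The default clustering used before compartment assignment and inside
#' [stability_profile()]: library-size log-normalization, selection of the
#' most variable genes, per-gene scaling, PCA, a shared-nearest-neighbor
#' graph with Jaccard weights, and modularity community detection (Louvain)
#' at the given resolution. Deterministic given `seed`.
#'
#' @param dataset A `SingleCellExperiment` with a `counts` assay.
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed controlling PCA initialization and community
#'   detection.
#' @param n_pcs Number of principal components (truncated to the data size).
#' @param k Nearest-neighbor count for the SNN graph (truncated with a
#'   warning when `k >= n_cells`).
#' @param n_hvg Number of highly variable genes retained.
#' @param prune Jaccard weights below this value are dropped.
#' @return A `cluster_labeling`: integer labels named by barcode, with the
#'   resolution and seed recorded.
#' @export
default_cluster <- function(dataset, resolution = 1, seed = 1L,
                            n_pcs = 50L, k = 20L, n_hvg = 2000L,
                            prune = 1 / 15) {
  counts <- .counts(dataset)
  n <- ncol(counts)
  if (n < 2L) stop("need at least 2 cells to cluster", call. = FALSE)
  if (k >= n) {
    warning(sprintf("k = %d >= n_cells = %d; truncating", k, n))
    k <- n - 1L
  }
  norm <- normalize_log(counts)

  v <- .row_vars(norm)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(norm)))]
  x <- t(as.matrix(norm[keep, , drop = FALSE]))
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0

  d <- min(n_pcs, n - 1L, ncol(x) - 1L)
  set.seed(seed)
  pcs <- if (d < min(dim(x)) / 3 && min(dim(x)) > 200L) {
    irlba::prcomp_irlba(x, n = d, center = FALSE, scale. = FALSE)$x
  } else {
    stats::prcomp(x, center = FALSE, scale. = FALSE)$x[, seq_len(d),
                                                       drop = FALSE]
  }

  nn <- RANN::nn2(pcs, k = k + 1L)$nn.idx[, -1L, drop = FALSE]
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0

  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- setNames(as.integer(igraph::membership(comm)), colnames(counts))
  structure(list(labels = labels, resolution = resolution, seed = seed),
            class = "cluster_labeling")
}

.row_vars <- function(m) {
  means <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - means^2
}

#' Cluster-stability profile over a resolution grid
#'
#' For each resolution: cluster the full data once, then repeat `n_iter`
#' times: subsample `floor(frac * n)` cells without replacement, recluster
#' with a fresh derived seed, and compute the adjusted Rand index between the
#' subsample labeling and the full-data labeling restricted to the subsample.
#' The default grid mirrors common practice (0.2 to 2.0 in steps of 0.2);
#' 90% retention over 20 iterations is the canonical setting.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param resolutions Ascending numeric vector of resolutions to profile.
#' @param frac Fraction of cells retained per subsample, in (0, 1\].
#' @param n_iter Subsample iterations per resolution.
#' @param cluster_fn Function `(dataset, resolution, seed) -> labels`;
#'   defaults to [default_cluster()].
#' @param seed Master seed; per-(resolution, iteration) seeds are derived
#'   from it so runs are reproducible and iterations independent.
#' @return A `stability_curve`: data frame `values` (resolution, iteration,
#'   ari) plus per-resolution `medians`.
#' @export
stability_profile <- function(dataset, resolutions = seq(0.2, 2, by = 0.2),
                              frac = 0.9, n_iter = 20L,
                              cluster_fn = default_cluster, seed = 1L) {
  stopifnot(frac > 0, frac <= 1, n_iter >= 1,
            !is.unsorted(resolutions), length(resolutions) >= 1L)
  barcodes <- colnames(dataset)
  n <- length(barcodes)
  n_sub <- floor(frac * n)
  if (n_sub < 2L) stop("subsample would have fewer than 2 cells", call. = FALSE)

  rows <- vector("list", length(resolutions) * n_iter)
  idx <- 0L
  for (ri in seq_along(resolutions)) {
    res <- resolutions[ri]
    full <- tryCatch(
      cluster_fn(dataset, res, .derive_seed(seed, ri, 0L)),
      error = function(e) stop(sprintf("cluster_fn failed at resolution %g (full data): %s",
                                       res, conditionMessage(e)), call. = FALSE))
    full_labels <- if (inherits(full, "cluster_labeling")) full$labels else full
    if (is.null(names(full_labels))) names(full_labels) <- barcodes
    for (it in seq_len(n_iter)) {
      it_seed <- .derive_seed(seed, ri, it)
      set.seed(it_seed)
      sub_cells <- sort(sample.int(n, n_sub))
      sub <- dataset[, sub_cells]
      lab <- tryCatch(
        cluster_fn(sub, res, .derive_seed(seed, ri, it, 1L)),
        error = function(e) stop(sprintf("cluster_fn failed at resolution %g, iteration %d: %s",
                                         res, it, conditionMessage(e)),
                                 call. = FALSE))
      sub_labels <- if (inherits(lab, "cluster_labeling")) lab$labels else lab
      if (is.null(names(sub_labels))) names(sub_labels) <- barcodes[sub_cells]
      ari <- adjusted_rand_index(full_labels[barcodes[sub_cells]], sub_labels)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(resolution = res, iteration = it, ari = ari)
    }
  }
  values <- do.call(rbind, rows)
  medians <- vapply(split(values$ari, values$resolution), median, 0)
  medians <- medians[order(as.numeric(names(medians)))]
  structure(list(values = values, medians = medians,
                 resolutions = resolutions, frac = frac, n_iter = n_iter,
                 seed = seed),
            class = "stability_curve")
}

#' Select the clustering resolution from a stability curve
#'
#' Scans per-resolution median ARI values in ascending resolution order and
#' returns the resolution immediately preceding the first drop larger than
#' `tolerance` (the largest resolution before the index starts decreasing).
#' If no such drop occurs the largest tested resolution is returned. The
#' tolerance absorbs subsampling jitter in the medians; the choice is a pure
#' function of the curve.
#'
#' @param curve A `stability_curve`, or a numeric vector of median ARI values
#'   named by resolution.
#' @param tolerance Minimum median decrease counted as "started decreasing".
#' @return The selected resolution (numeric scalar).
#' @export
select_resolution <- function(curve, tolerance = 0.01) {
  medians <- if (inherits(curve, "stability_curve")) curve$medians else curve
  if (length(medians) == 0L) stop("empty stability curve", call. = FALSE)
  res <- as.numeric(names(medians))
  if (anyNA(res)) stop("median vector must be named by resolution", call. = FALSE)
  o <- order(res)
  res <- res[o]
  medians <- medians[o]
  if (length(medians) > 1L) {
    for (i in seq_len(length(medians) - 1L)) {
      if (medians[i + 1L] < medians[i] - tolerance) return(res[i])
    }
  }
  res[length(res)]
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("Stability curve: %d resolutions x %d iterations (frac = %.2f)\n",
              length(x$resolutions), x$n_iter, x$frac))
  print(round(x$medians, 4))
  invisible(x)
}
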