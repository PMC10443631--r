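#' @importFrom stats median mad quantile var
NULL

#' Quality-control thresholds
#'
#' Defaults follow the study design for mouse bone-marrow, meningeal and
#' brain samples: mitochondrial read fraction caps of 0.2 (bone), 0.3
#' (meninges) and 0.6 (brain); minimum UMI of 1000 (bone) and 500
#' (meninges, brain); a global 50,000 UMI ceiling; genes expressed in fewer
#' than 10 surviving cells dropped; and removal of cells with doublet score
#' above 0.1. No minimum-gene filter is applied (erythroid cells express few
#' genes).
#'
#' @param mito_max named per-tissue-class fractions.
#' @param umi_min named per-tissue-class integers.
#' @param umi_max global UMI ceiling.
#' @param min_cells_per_gene gene filter support.
#' @param doublet_max doublet-score ceiling.
#' @return a list of class `qc_thresholds`.
#' @export
qcThresholds <- function(mito_max = c(bone = 0.2, meninges = 0.3, brain = 0.6),
                         umi_min = c(bone = 1000, meninges = 500, brain = 500),
                         umi_max = 50000,
                         min_cells_per_gene = 10,
                         doublet_max = 0.1) {
  stopifnot(all(mito_max > 0), all(mito_max <= 1),
            all(umi_min < umi_max), min_cells_per_gene >= 0,
            doublet_max >= 0, doublet_max <= 1)
  structure(list(mito_max = mito_max, umi_min = umi_min, umi_max = umi_max,
                 min_cells_per_gene = min_cells_per_gene,
                 doublet_max = doublet_max),
            class = "qc_thresholds")
}

#' Apply quality-control filters
#'
#' Removes cells failing their tissue-class-specific thresholds, in the
#' fixed order mito fraction, minimum UMI, maximum UMI, doublet score (each
#' removed cell attributed to the first filter that catches it), then drops
#' genes expressed (count > 0) in fewer than `min_cells_per_gene` of the
#' surviving cells. Derived per-cell fields are recomputed on the filtered
#' matrix. The operation is idempotent on cohorts whose low-support genes
#' carry negligible counts.
#'
#' @param cohort a [MarrowCohort-class] with `tissue_class` set per cell.
#' @param thresholds a [qcThresholds()] list.
#' @return a list with elements `cohort` (filtered) and `report` (data.frame
#'   with one row per filter plus in/out totals).
#' @export
applyQC <- function(cohort, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  cd <- colData(cohort)
  tc <- as.character(cd$tissue_class)
  known <- union(names(thresholds$mito_max), names(thresholds$umi_min))
  bad <- setdiff(unique(tc), known)
  if (length(bad))
    stop("unknown tissue_class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_cells <- ncol(cohort)
  removed_by <- rep(NA_character_, n_cells)
  fail_mito <- cd$mito_fraction > thresholds$mito_max[tc]
  fail_umin <- cd$total_umi < thresholds$umi_min[tc]
  fail_umax <- cd$total_umi > thresholds$umi_max
  fail_dbl <- cd$doublet_score > thresholds$doublet_max
  removed_by[fail_dbl] <- "doublet"
  removed_by[fail_umax] <- "umi_max"
  removed_by[fail_umin] <- "umi_min"
  removed_by[fail_mito] <- "mito"
  keep_cells <- is.na(removed_by)
  counts <- assay(cohort, "counts")[, keep_cells, drop = FALSE]
  n_expr <- Matrix::rowSums(counts > 0)
  keep_genes <- n_expr >= thresholds$min_cells_per_gene
  report <- data.frame(
    filter = c("mito", "umi_min", "umi_max", "doublet", "gene_min_cells"),
    removed_cells = c(sum(removed_by == "mito", na.rm = TRUE),
                      sum(removed_by == "umi_min", na.rm = TRUE),
                      sum(removed_by == "umi_max", na.rm = TRUE),
                      sum(removed_by == "doublet", na.rm = TRUE), 0L),
    removed_genes = c(0L, 0L, 0L, 0L, sum(!keep_genes)),
    stringsAsFactors = FALSE)
  attr(report, "cells_in") <- n_cells
  attr(report, "cells_out") <- sum(keep_cells)
  attr(report, "genes_in") <- nrow(cohort)
  attr(report, "genes_out") <- sum(keep_genes)
  out <- MarrowCohort(counts[keep_genes, , drop = FALSE],
                      as.data.frame(cd[keep_cells, , drop = FALSE]),
                      as.data.frame(rowData(cohort)[keep_genes, ,
                                                    drop = FALSE]))
  list(cohort = out, report = report)
}

# exact thin SVD of the (optionally centered) cells x genes matrix,
# component signs fixed by the largest-magnitude loading
.pca_core <- function(x, n_components, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("PCA requires at least 2 cells", call. = FALSE)
  if (center) x <- sweep(x, 2, colMeans(x))
  k <- min(n_components, n - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  scores <- sv$u %*% diag(d, k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, eigenvalues = d^2 / (n - 1), loadings = loadings)
}

#' Cluster cells for size-factor computation
#'
#' Partitions the cells for per-cluster normalization: counts are
#' total-count normalized to 10,000 per cell and log1p-transformed, a PCA is
#' computed, a shared-nearest-neighbor graph over `k_neighbors` neighbors is
#' built (via scran), communities are detected by Louvain modularity
#' optimization, and clusters smaller than `min_cluster` cells are merged
#' into the neighboring cluster with the largest total connecting edge
#' weight. Cohorts smaller than `2 * min_cluster` cells collapse to a single
#' cluster.
#'
#' @param cohort a [MarrowCohort-class].
#' @param k_neighbors neighbors for the SNN graph (default 30).
#' @param min_cluster minimum cluster size (default 100).
#' @param n_components PCA dimensionality for the graph (default 50).
#' @param seed integer seed (community detection breaks ties randomly).
#' @return an integer factor of cluster labels, one per cell.
#' @export
clusterForSizeFactors <- function(cohort, k_neighbors = 30L,
                                  min_cluster = 100L, n_components = 50L,
                                  seed = 1L) {
  n <- ncol(cohort)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (n < 2 * min_cluster) return(factor(rep(1L, n)))
  counts <- assay(cohort, "counts")
  tot <- pmax(Matrix::colSums(counts), 1)
  norm <- counts %*% Matrix::Diagonal(x = 10000 / tot)
  norm@x <- log1p(norm@x)
  pc <- .pca_core(Matrix::t(norm), n_components)
  k_use <- min(k_neighbors, n - 1L)
  with_seed(seed, {
    g <- scran::buildSNNGraph(pc$scores, k = k_use, transposed = TRUE,
                              d = NA)
    cl <- igraph::membership(igraph::cluster_louvain(g))
    adj <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
    cl <- merge_small_clusters(as.integer(cl), adj, min_cluster)
    factor(cl)
  })
}

merge_small_clusters <- function(cl, adj, min_cluster) {
  repeat {
    sizes <- table(cl)
    if (length(sizes) <= 1 || all(sizes >= min_cluster)) break
    small <- names(sizes)[sizes < min_cluster]
    victim <- small[which.min(sizes[small])]
    in_v <- cl == as.integer(victim)
    w <- Matrix::colSums(adj[in_v, , drop = FALSE])
    conn <- tapply(w, cl, sum)
    conn[victim] <- -Inf
    target <- names(conn)[which.max(conn)]
    cl[in_v] <- as.integer(target)
  }
  as.integer(factor(cl))
}

#' Cluster-based size factors
#'
#' For each cluster *c*, a composition factor
#' `theta_c = median over genes expressed in both profiles of
#' (cluster mean profile / overall mean profile)` is computed on raw counts;
#' each cell's size factor is
#' `s_i = theta_c(i) * total_umi_i / mean(total_umi over cluster c(i))`,
#' rescaled so that `mean(s) = 1`. All factors are strictly positive.
#'
#' @param cohort a [MarrowCohort-class].
#' @param clusters factor of cluster labels, one per cell.
#' @return numeric vector of size factors (mean 1).
#' @export
computeSizeFactors <- function(cohort, clusters) {
  clusters <- as.factor(clusters)
  stopifnot(length(clusters) == ncol(cohort))
  if (any(table(clusters) == 0)) clusters <- droplevels(clusters)
  counts <- assay(cohort, "counts")
  overall <- Matrix::rowMeans(counts)
  tot <- Matrix::colSums(counts)
  s <- numeric(ncol(cohort))
  for (lv in levels(clusters)) {
    in_c <- clusters == lv
    prof <- Matrix::rowMeans(counts[, in_c, drop = FALSE])
    both <- prof > 0 & overall > 0
    if (!any(both))
      stop("cluster '", lv, "' shares no expressed genes with the overall ",
           "profile", call. = FALSE)
    theta <- median(prof[both] / overall[both])
    s[in_c] <- theta * tot[in_c] / mean(tot[in_c])
  }
  if (any(s <= 0)) stop("non-positive size factor produced", call. = FALSE)
  s / mean(s)
}

#' Log-normalize counts by size factors
#'
#' Adds a `logcounts` assay with `log(count / s_i + 1)` (natural log) and
#' records the size factors (rescaled to mean 1) in `colData()$size_factor`.
#' Zero counts map to zero, preserving sparsity.
#'
#' @param cohort a [MarrowCohort-class].
#' @param size_factors positive numeric vector, one per cell; defaults to
#'   [computeSizeFactors()] over [clusterForSizeFactors()].
#' @return the cohort with the `logcounts` assay attached.
#' @export
logNormalize <- function(cohort, size_factors = NULL) {
  if (is.null(size_factors))
    size_factors <- computeSizeFactors(cohort,
                                       clusterForSizeFactors(cohort))
  stopifnot(length(size_factors) == ncol(cohort))
  if (any(!is.finite(size_factors)) || any(size_factors <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  size_factors <- size_factors / mean(size_factors)
  lc <- assay(cohort, "counts") %*% Matrix::Diagonal(x = 1 / size_factors)
  lc <- methods::as(lc, "CsparseMatrix")
  lc@x <- log1p(lc@x)
  dimnames(lc) <- dimnames(cohort)
  assay(cohort, "logcounts") <- lc
  colData(cohort)$size_factor <- size_factors
  cohort
}

logcounts_of <- function(cohort) {
  if (!"logcounts" %in% assayNames(cohort))
    stop("cohort has no 'logcounts' assay; run logNormalize() first",
         call. = FALSE)
  assay(cohort, "logcounts")
}

#' Per-sample highly variable gene selection
#'
#' For each sample, per-gene mean and dispersion (variance/mean) of the
#' de-logged (`expm1`) normalized values are computed; genes are binned into
#' `n_bins` mean-quantile bins and each gene's dispersion is normalized by
#' its bin's median and median absolute deviation. The `n_per_sample` genes
#' with the highest normalized dispersion are selected per sample. The
#' combined set ranks genes by the number of supporting samples, ties broken
#' by median normalized dispersion, truncated to `n_per_sample`. Constant
#' genes are never selected. Samples with fewer than 2 cells are skipped
#' with a warning.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param sample_col colData column defining samples (default `sample_id`).
#' @param n_per_sample genes kept per sample (default 4000).
#' @param n_bins mean bins for dispersion normalization (default 20).
#' @return a list with `per_sample` (named list of ranked data.frames) and
#'   `combined` (data.frame: `gene_id`, `support`, `median_norm_dispersion`).
#' @export
selectHVGs <- function(cohort, sample_col = "sample_id",
                       n_per_sample = 4000L, n_bins = 20L) {
  stopifnot(n_bins >= 1)
  lc <- logcounts_of(cohort)
  samples <- as.character(colData(cohort)[[sample_col]])
  per_sample <- list()
  for (s in unique(samples)) {
    in_s <- samples == s
    if (sum(in_s) < 2) {
      warning("sample '", s, "' has fewer than 2 cells; skipped")
      next
    }
    x <- expm1(as.matrix(lc[, in_s, drop = FALSE]))
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    ok <- m > 0 & v > 0
    disp <- rep(NA_real_, nrow(x))
    disp[ok] <- v[ok] / m[ok]
    nd <- rep(NA_real_, nrow(x))
    if (any(ok)) {
      br <- unique(quantile(m[ok], probs = seq(0, 1, length.out = n_bins + 1)))
      bin <- cut(m[ok], breaks = br, include.lowest = TRUE)
      for (b in levels(bin)) {
        in_b <- which(ok)[bin == b]
        if (!length(in_b)) next
        md <- median(disp[in_b])
        sd_b <- mad(disp[in_b], constant = 1)
        if (sd_b == 0) sd_b <- .Machine$double.eps
        nd[in_b] <- (disp[in_b] - md) / sd_b
      }
    }
    df <- data.frame(gene_id = rownames(cohort), mean = m, dispersion = disp,
                     norm_dispersion = nd, stringsAsFactors = FALSE)
    df <- df[!is.na(df$norm_dispersion), , drop = FALSE]
    df <- df[order(-df$norm_dispersion, df$gene_id), , drop = FALSE]
    df <- utils::head(df, n_per_sample)
    df$rank <- seq_len(nrow(df))
    per_sample[[s]] <- df
  }
  if (!length(per_sample))
    stop("no sample with at least 2 cells", call. = FALSE)
  all_sel <- do.call(rbind, lapply(per_sample, function(d)
    d[, c("gene_id", "norm_dispersion")]))
  support <- table(all_sel$gene_id)
  med_nd <- tapply(all_sel$norm_dispersion, all_sel$gene_id, median)
  combined <- data.frame(gene_id = names(support),
                         support = as.integer(support),
                         median_norm_dispersion = as.numeric(med_nd[names(support)]),
                         stringsAsFactors = FALSE)
  combined <- combined[order(-combined$support,
                             -combined$median_norm_dispersion,
                             combined$gene_id), , drop = FALSE]
  combined <- utils::head(combined, n_per_sample)
  rownames(combined) <- NULL
  list(per_sample = per_sample, combined = combined)
}

#' Exact PCA of the log-normalized layer
#'
#' Computes the thin singular-value decomposition of the centered
#' cells-by-genes matrix restricted to a gene subset. Explained variances
#' are `singular_value^2 / (cells - 1)`; component signs are fixed so the
#' largest-magnitude loading of each component is positive, making the
#' result deterministic.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param genes gene ids to use (default: all genes).
#' @param n_components maximum components (default 50; capped at
#'   `min(cells - 1, genes)`).
#' @param center center columns before decomposition (default TRUE).
#' @param cells optional logical/integer subset of cells.
#' @return a [CohortPCA-class].
#' @export
computePCA <- function(cohort, genes = NULL, n_components = 50L,
                       center = TRUE, cells = NULL) {
  lc <- logcounts_of(cohort)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  if (is.null(genes)) genes <- rownames(cohort)
  miss <- setdiff(genes, rownames(cohort))
  if (length(miss))
    stop("genes not in cohort: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  x <- Matrix::t(lc[genes, , drop = FALSE])
  pc <- .pca_core(x, n_components, center)
  rownames(pc$scores) <- rownames(x)
  rownames(pc$loadings) <- genes
  methods::new("CohortPCA", scores = pc$scores,
               eigenvalues = pc$eigenvalues, loadings = pc$loadings,
               genes = as.character(genes))
}
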