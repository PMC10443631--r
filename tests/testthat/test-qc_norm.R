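test_that("QC matches the hand-enumerated oracle and is idempotent", {
  fx <- qc_fixture()
  orc <- oracle_qc(fx$cohort, fx$thr)
  expect_equal(sum(!orc$keep), 4)     # fixture built to drop exactly 4 cells
  expect_equal(sum(!orc$genes_keep), 2)
  res <- applyQC(fx$cohort, fx$thr)
  expect_equal(colnames(res$cohort), colnames(fx$cohort)[orc$keep])
  expect_equal(rownames(res$cohort), rownames(fx$cohort)[orc$genes_keep])
  tab <- table(orc$why)
  for (f in names(tab))
    expect_equal(res$report$removed_cells[res$report$filter == f],
                 as.integer(tab[f]))
  expect_equal(attr(res$report, "cells_out"), 8)
  expect_equal(attr(res$report, "genes_out"), 4)
  # idempotence
  res2 <- applyQC(res$cohort, fx$thr)
  expect_identical(as.matrix(assay(res2$cohort, "counts")),
                   as.matrix(assay(res$cohort, "counts")))
  expect_equal(sum(res2$report$removed_cells), 0)
  expect_equal(sum(res2$report$removed_genes), 0)
})

test_that("mito thresholds are tissue-class specific", {
  counts <- matrix(c(25, 75, 25, 75), nrow = 2)   # mito fraction 0.25 both
  cells <- make_cell_table(2)
  cells$tissue_class <- c("bone", "brain")
  genes <- make_gene_table(2)
  genes$is_mito <- c(TRUE, FALSE)
  coh <- MarrowCohort(counts, cells, genes)
  res <- applyQC(coh, qcThresholds(umi_min = c(bone = 1, meninges = 1,
                                               brain = 1),
                                   min_cells_per_gene = 0))
  expect_equal(colnames(res$cohort), "c002")  # brain cell kept at 0.25
  expect_error(applyQC(MarrowCohort(counts,
                                    within(cells, tissue_class <- "skin"),
                                    genes)),
               "skin")
})

test_that("empty cohorts pass QC with all-zero reports", {
  coh <- MarrowCohort(matrix(0L, 0, 0), make_cell_table(0),
                      make_gene_table(0))
  res <- applyQC(coh)
  expect_equal(ncol(res$cohort), 0)
  expect_true(all(res$report$removed_cells == 0))
  expect_true(all(res$report$removed_genes == 0))
})

test_that("size factors honor symmetry, depth scaling, and the formula", {
  # identical cells -> all factors 1
  counts <- matrix(rep(c(5L, 3L, 2L), 4), nrow = 3)
  coh <- MarrowCohort(counts, make_cell_table(4), make_gene_table(3))
  expect_equal(computeSizeFactors(coh, factor(rep(1, 4))), rep(1, 4))

  # cell B = 2 x cell A in the same cluster -> factor ratio 2
  counts2 <- cbind(c(5L, 3L, 2L), c(10L, 6L, 4L), c(5L, 3L, 2L))
  coh2 <- MarrowCohort(counts2, make_cell_table(3), make_gene_table(3))
  s <- computeSizeFactors(coh2, factor(rep(1, 3)))
  expect_equal(s[2] / s[1], 2)

  # two-cluster fixture vs term-by-term formula evaluation
  set.seed(5)
  counts3 <- cbind(matrix(rpois(5 * 6, 8), nrow = 6),
                   matrix(rpois(5 * 6, 2), nrow = 6))
  coh3 <- MarrowCohort(counts3, make_cell_table(10), make_gene_table(6))
  cl <- factor(rep(c("a", "b"), each = 5))
  got <- computeSizeFactors(coh3, cl)
  overall <- rowMeans(counts3)
  raw <- numeric(10)
  for (g in c("a", "b")) {
    in_g <- cl == g
    prof <- rowMeans(counts3[, in_g, drop = FALSE])
    both <- prof > 0 & overall > 0
    theta <- median(prof[both] / overall[both])
    tot <- colSums(counts3)
    raw[in_g] <- theta * tot[in_g] / mean(tot[in_g])
  }
  expect_equal(got, raw / mean(raw))
})

test_that("size factors scale with per-cell depth", {
  set.seed(6)
  n <- 200
  base <- matrix(rpois(n * 20, 5), nrow = 20)
  for (c_mult in c(2, 5)) {
    counts <- base
    counts[, 1] <- counts[, 1] * c_mult
    coh <- MarrowCohort(counts, make_cell_table(n), make_gene_table(20))
    s <- computeSizeFactors(coh, factor(rep(1, n)))
    s0 <- computeSizeFactors(MarrowCohort(base, make_cell_table(n),
                                          make_gene_table(20)),
                             factor(rep(1, n)))
    expect_lt(abs(s[1] / s0[1] / c_mult - 1), 0.05)
  }
})

test_that("log-normalization is the elementwise closed form", {
  counts <- cbind(c(0L, 3L, 7L), c(1L, 0L, 2L))
  coh <- MarrowCohort(counts, make_cell_table(2), make_gene_table(3))
  norm <- logNormalize(coh, c(1, 1))
  lc <- as.matrix(assay(norm, "logcounts"))
  expect_equal(lc[1, 1], 0)
  expect_equal(lc[2, 1], log(4))
  # random fixture vs independent elementwise evaluation
  coh2 <- random_cohort(15, 10, seed = 8)
  s <- runif(15, 0.5, 2)
  s <- s / mean(s)
  norm2 <- logNormalize(coh2, s)
  manual <- log1p(sweep(as.matrix(assay(coh2, "counts")), 2, s, "/"))
  expect_equal(as.matrix(assay(norm2, "logcounts")), manual,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(logNormalize(coh2, rep(-1, 15)), "positive")
})

test_that("community clustering recovers separated profiles", {
  # homogeneous profile -> one cluster
  cfg <- simConfig(regions = "a", cells_per_sample = 150, n_genes = 120,
                   seed = 9)
  coh <- simulateCohort(cfg)$cohort
  cl <- clusterForSizeFactors(coh, min_cluster = 60)
  expect_equal(nlevels(cl), 1)
  # 50 cells: below 2 x min_cluster -> single cluster without clustering
  expect_equal(nlevels(clusterForSizeFactors(coh[, 1:50])), 1)
  # two well-separated types x 200 cells
  cfg2 <- simConfig(regions = "a", cells_per_sample = 400,
                    cell_types = c("t1", "t2"), marker_genes_per_type = 30,
                    marker_fold = 12, n_genes = 200, seed = 10)
  sim2 <- simulateCohort(cfg2)
  cl2 <- clusterForSizeFactors(sim2$cohort, min_cluster = 100)
  expect_equal(nlevels(cl2), 2)
  agree <- max(vapply(levels(cl2), function(l)
    mean((cl2 == l) == (sim2$truth$true_cell_type == "t1")), numeric(1)))
  expect_gte(agree, 0.99)
})

test_that("HVG selection finds planted dispersion and is order-invariant", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80; g <- 60
    counts <- matrix(rpois(n * g, 5), nrow = g)
    # gene 30: strongly overdispersed mixture at the same mean
    counts[30, ] <- ifelse(runif(n) < 0.1, rpois(n, 46), rpois(n, 0.4))
    counts[10, ] <- 7L                       # constant gene
    cells <- make_cell_table(n)
    cells$sample_id <- rep(c("s1", "s2"), each = n / 2)
    coh <- logNormalize(MarrowCohort(counts, cells, make_gene_table(g)),
                        rep(1, n))
    hv <- selectHVGs(coh, n_per_sample = 10, n_bins = 5)
    expect_false("g010" %in% hv$combined$gene_id)
    if ("g030" %in% hv$combined$gene_id) hits <- hits + 1
    if (seed == 1) {
      # permuting gene rows must not change the selected set
      perm <- sample(g)
      coh_p <- logNormalize(MarrowCohort(counts[perm, , drop = FALSE],
                                         cells,
                                         make_gene_table(g)[perm, ]),
                            rep(1, n))
      hv_p <- selectHVGs(coh_p, n_per_sample = 10, n_bins = 5)
      expect_setequal(hv_p$combined$gene_id, hv$combined$gene_id)
    }
  }
  expect_equal(hits, 10)
})

test_that("HVG truncation keeps all non-constant genes when n is large", {
  coh <- quick_normalize(random_cohort(30, 12, seed = 12))
  hv <- selectHVGs(coh, n_per_sample = 1000)
  lc <- as.matrix(assay(coh, "logcounts"))
  n_nonconst <- sum(apply(expm1(lc), 1, var) > 0 & rowMeans(expm1(lc)) > 0)
  expect_equal(nrow(hv$combined), n_nonconst)
})

test_that("PCA satisfies conservation, orthonormality, and the eigen oracle", {
  # rank-1 data
  n <- 20
  line <- outer(seq_len(n), c(1, 2, 3))
  counts <- t(round(line))
  coh <- quick_normalize(MarrowCohort(counts, make_cell_table(n),
                                      make_gene_table(3)))
  # overwrite logcounts with exact rank-1 values for the analytic case
  assay(coh, "logcounts") <- Matrix::Matrix(t(line), sparse = TRUE,
                                            dimnames = dimnames(coh))
  pca <- computePCA(coh, n_components = 3)
  expect_lt(max(abs(pca@eigenvalues[-1])), 1e-10)

  coh2 <- quick_normalize(random_cohort(30, 10, seed = 13))
  pca2 <- computePCA(coh2, n_components = 10)
  lc <- as.matrix(Matrix::t(assay(coh2, "logcounts")))
  centered <- sweep(lc, 2, colMeans(lc))
  expect_equal(sum(pca2@eigenvalues), sum(apply(centered, 2, var)),
               tolerance = 1e-8)
  gram <- crossprod(pca2@loadings)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # brute-force covariance eigendecomposition oracle
  ev <- eigen(cov(centered), symmetric = TRUE)
  expect_equal(pca2@eigenvalues, ev$values[seq_along(pca2@eigenvalues)],
               tolerance = 1e-8)
  sc_oracle <- centered %*% ev$vectors
  for (j in 1:5)
    expect_equal(abs(pca2@scores[, j]), abs(sc_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(computePCA(coh2[, 1]), "2 cells")
})
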