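test_that("with two regions both tests collapse to the same comparison", {
  coh <- normalized_cohort(n_per_region = 15,
                           regions = c("calvaria", "femur"), seed = 1)
  res <- gapSplitTest(coh, "g005")
  expect_equal(res$p_final, res$p_group)
  expect_equal(res$p_boundary, res$p_group)
  expect_equal(res$lfc_final, res$lfc_group)
  expect_equal(res$split_index, 1L)
})

test_that("gap-split agrees exactly with the exhaustive-split oracle", {
  set.seed(14)
  for (rep in 1:25) {
    n_regions <- sample(3:6, 1)
    regions <- paste0("r", seq_len(n_regions))
    n_per <- sample(5:20, n_regions, replace = TRUE)
    labs <- rep(regions, n_per)
    n <- length(labs)
    vals <- round(rnorm(n, mean = rep(runif(n_regions, 0, 3), n_per),
                        sd = 0.7), 3)
    vals <- pmax(vals, 0)
    counts <- matrix(0L, nrow = 1, ncol = n)
    cells <- make_cell_table(n)
    cells$region <- labs
    coh <- MarrowCohort(counts + 1L, cells, make_gene_table(1))
    lcm <- Matrix::Matrix(matrix(vals, nrow = 1), sparse = TRUE,
                          dimnames = dimnames(coh))
    assay(coh, "logcounts") <- lcm
    got <- gapSplitTest(coh, "g001")
    orc <- oracle_gap_split(vals, labs)
    expect_equal(got$split_index, orc$k_star)
    expect_equal(strsplit(got$ordered_regions, ",")[[1]], orc$ordered)
    expect_setequal(strsplit(got$high_group, ",")[[1]], orc$high)
    expect_setequal(strsplit(got$low_group, ",")[[1]], orc$low)
    expect_equal(got$p_group, orc$p_group, tolerance = 1e-12)
    expect_equal(got$p_boundary, orc$p_boundary, tolerance = 1e-12)
    expect_equal(got$lfc_group, orc$lfc_group, tolerance = 1e-12)
    expect_equal(got$lfc_boundary, orc$lfc_boundary, tolerance = 1e-12)
    # combination laws
    expect_gte(got$p_final, got$p_group)
    expect_gte(got$p_final, got$p_boundary)
    expect_lte(got$lfc_final, got$lfc_group)
    expect_lte(got$lfc_final, got$lfc_boundary)
  }
})

test_that("a dominant-top-region mean pattern splits after rank one", {
  means <- c(5.0, 1.2, 1.0, 0.9, 0.8, 0.7)
  regions <- paste0("r", 1:6)
  labs <- rep(regions, each = 30)
  set.seed(15)
  vals <- pmax(rnorm(length(labs), rep(means, each = 30), 0.2), 0)
  counts <- matrix(1L, nrow = 1, ncol = length(labs))
  cells <- make_cell_table(length(labs))
  cells$region <- labs
  coh <- MarrowCohort(counts, cells, make_gene_table(1))
  assay(coh, "logcounts") <- Matrix::Matrix(matrix(vals, nrow = 1),
                                            sparse = TRUE,
                                            dimnames = dimnames(coh))
  got <- gapSplitTest(coh, "g001")
  expect_equal(got$split_index, 1L)
  expect_equal(got$high_group, "r1")
  orc <- oracle_gap_split(vals, labs)
  expect_equal(got$p_final, orc$p_final, tolerance = 1e-12)
})

test_that("DEG calls follow the declared thresholds", {
  coh <- normalized_cohort(n_per_region = 20, seed = 16)
  res <- runCombinatorialDE(coh)
  expect_equal(res$is_deg,
               res$p_final < 0.05 & res$lfc_final > 1)
  relaxed <- runCombinatorialDE(coh, deThresholds(lfc_min = 0.5))
  expect_equal(relaxed$is_deg,
               relaxed$p_final < 0.05 & relaxed$lfc_final > 0.5)
  # the relaxed neutrophil threshold can only add calls
  expect_true(all(res$is_deg <= relaxed$is_deg))
})

test_that("combinatorial DE recovers planted genes with correct direction", {
  cfg <- simConfig(regions = paste0("r", 1:4), cells_per_sample = 250,
                   n_genes = 300, seed = 17)
  planted <- sprintf("g%04d", 101:120)  # away from the marker block
  eff <- plantedEffects(planted, "r2", log2_fold = 2)
  coh <- quick_normalize(simulateCohort(cfg, eff)$cohort)
  res <- runCombinatorialDE(coh)
  hits <- res$gene_id[res$is_deg]
  sens <- mean(planted %in% hits)
  fdp <- if (length(hits)) mean(!hits %in% planted) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
  # planted genes are called up in r2 alone
  up <- res[res$gene_id %in% planted & res$is_deg, "high_group"]
  expect_true(all(up == "r2"))
  # permuting region labels destroys detection
  cd <- colData(coh)
  set.seed(18)
  cd$region <- sample(as.character(cd$region))
  colData(coh) <- cd
  res_perm <- runCombinatorialDE(coh)
  expect_lte(mean(planted %in% res_perm$gene_id[res_perm$is_deg]), 0.1)
})

test_that("null cohorts stay near the nominal combinatorial DE rate", {
  fp <- vapply(1:5, function(seed) {
    cfg <- simConfig(regions = paste0("r", 1:4), cells_per_sample = 100,
                     n_genes = 200, seed = 500 + seed)
    coh <- quick_normalize(nullCohort(cfg)$cohort)
    res <- runCombinatorialDE(coh)
    mean(res$is_deg)
  }, numeric(1))
  # the joint p<0.05 & LFC>1 rule is conservative; 2x nominal is the bound
  expect_lte(mean(fp), 0.1)
})

test_that("grouped t-tests match t.test and brute-force BH", {
  coh <- normalized_cohort(n_per_region = 30, seed = 19)
  group <- rep(c("naive", "mcao"), length.out = ncol(coh))
  genes <- rownames(coh)[1:12]
  expect_warning(res <- groupedTTestBH(coh, c(genes, "absent"), group),
                 "absent")
  lc <- as.matrix(assay(coh, "logcounts"))
  for (g in genes[1:4]) {
    tt <- t.test(lc[g, group == "mcao"], lc[g, group == "naive"])
    expect_equal(res$p[res$gene_id == g], tt$p.value, tolerance = 1e-12)
    expect_equal(res$t[res$gene_id == g], unname(tt$statistic),
                 tolerance = 1e-12)
  }
  tested <- !is.na(res$p)
  expect_equal(res$p_adj[tested], oracle_bh(res$p[tested]),
               tolerance = 1e-12)
  expect_true(all(res$p_adj[tested] >= res$p[tested]))
  expect_true(is.na(res$p[res$gene_id == "absent"]))

  # identical groups -> t = 0, p = 1
  dup <- coh[, c(1:20, 1:20)]
  res_dup <- groupedTTestBH(dup, genes,
                            rep(c("a", "b"), each = 20))
  expect_true(all(res_dup$t == 0))
  expect_true(all(res_dup$p == 1))
})

test_that("a planted condition-responsive gene ranks first", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 120
    g <- 20
    counts <- matrix(rpois(n * g, 4), nrow = g)
    group <- rep(c("naive", "mcao"), each = n / 2)
    counts[7, group == "mcao"] <- rpois(n / 2, 10)
    cells <- make_cell_table(n)
    cells$condition <- group
    coh <- quick_normalize(MarrowCohort(counts, cells, make_gene_table(g)))
    res <- groupedTTestBH(coh, rownames(coh), group)
    if (res$gene_id[which.min(res$p_adj)] == "g007") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("gene-set scores are row means with verbatim default sets", {
  sets <- inflammatoryGeneSets()
  expect_identical(sets$pro_inflammatory,
                   c("Il6", "Il1a", "Il1b", "Ifng", "Il11", "Il7d", "Il7f",
                     "Il18", "Tnf"))
  expect_identical(sets$anti_inflammatory,
                   c("Il1rn", "Tgfb1", "Il4", "Il10", "Il12a", "Il13"))

  counts <- matrix(1L, nrow = 3, ncol = 3)
  cells <- make_cell_table(3)
  coh <- MarrowCohort(counts, cells, make_gene_table(3))
  vals <- rbind(c(1, 0, 2), c(3, 0, 4), c(9, 9, 9))
  assay(coh, "logcounts") <- Matrix::Matrix(vals, sparse = TRUE,
                                            dimnames = dimnames(coh))
  expect_warning(
    gs <- geneSetScore(coh, "demo", c("g001", "g002", "ghost"),
                       group = c("a", "a", "b")),
    "ghost")
  expect_equal(gs$cell_score, c(2, 0, 3))
  expect_equal(gs$summary$mean[gs$summary$group == "a"], 1)
  expect_equal(gs$summary$mean[gs$summary$group == "b"], 3)
  expect_error(geneSetScore(coh, "none", "ghost", group = c("a", "a", "b")),
               "none of the listed genes")
})

test_that("proportions are gated to parents before correlating", {
  counts <- rbind(s1 = c(t_a = 30, t_b = 30, t_c = 240),
                  s2 = c(t_a = 10, t_b = 50, t_c = 240))
  parent <- c(t_a = "lymphoid", t_b = "lymphoid", t_c = "myeloid")
  # a type at 30 of 60 cells under its parent -> 0.5, not 30/300
  ref <- rbind(s1 = c(t_a = 0.5, t_b = 0.5, t_c = 1),
               s2 = c(t_a = 1 / 6, t_b = 5 / 6, t_c = 1))
  res <- proportionCorrelation(counts, ref, parent)
  expect_equal(res$transformed["s1", "t_a"], 0.5)
  expect_equal(res$per_sample$r, c(1, 1))
  expect_equal(res$mean_r, 1)

  # randomized reference agrees with a direct covariance oracle
  set.seed(20)
  ref2 <- ref + matrix(runif(6), 2)
  res2 <- proportionCorrelation(counts, ref2, parent)
  for (i in 1:2)
    expect_equal(res2$per_sample$r[i],
                 cor(res2$transformed[i, ], ref2[i, ]), tolerance = 1e-12)

  # zero parent gate -> NA proportion, excluded pairwise
  counts3 <- counts
  counts3["s2", c("t_a", "t_b")] <- 0
  res3 <- proportionCorrelation(counts3, ref, parent)
  expect_true(all(is.na(res3$transformed["s2", c("t_a", "t_b")])))
})
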