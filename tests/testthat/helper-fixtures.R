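# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is loaded from disk except the bundled toy LR database.

make_cell_table <- function(n, region = "calvaria", condition = "naive",
                            cell_type = "neutrophil", sample_id = "s1",
                            tissue_class = "bone", doublet_score = 0) {
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             region = rep(region, length.out = n),
             condition = rep(condition, length.out = n),
             cell_type = rep(cell_type, length.out = n),
             sample_id = rep(sample_id, length.out = n),
             tissue_class = rep(tissue_class, length.out = n),
             doublet_score = rep(doublet_score, length.out = n),
             stringsAsFactors = FALSE)
}

make_gene_table <- function(g, n_mito = 0) {
  data.frame(gene_id = sprintf("g%03d", seq_len(g)),
             is_mito = seq_len(g) <= n_mito, stringsAsFactors = FALSE)
}

random_cohort <- function(n = 30, g = 20, seed = 1, n_mito = 2, ...) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, 3), nrow = g)
  cells <- make_cell_table(n, ...)
  cells$doublet_score <- runif(n, 0, 0.09)
  MarrowCohort(counts, cells, make_gene_table(g, n_mito))
}

# cohort with unit size factors and a logcounts layer, multiple regions
normalized_cohort <- function(n_per_region = 40, g = 30,
                              regions = c("calvaria", "femur", "humerus"),
                              seed = 1) {
  set.seed(seed)
  n <- n_per_region * length(regions)
  counts <- matrix(rpois(n * g, 4), nrow = g)
  cells <- make_cell_table(n)
  cells$region <- rep(regions, each = n_per_region)
  cells$sample_id <- cells$region
  coh <- MarrowCohort(counts, cells, make_gene_table(g))
  logNormalize(coh, rep(1, n))
}

# independent brute-force divergence score: literal per-component lm fits
oracle_variance_explained <- function(scores, eigenvalues, group) {
  y <- as.numeric(as.factor(group)) - 1
  keep <- eigenvalues > 0
  r2 <- vapply(which(keep), function(j) {
    fit <- stats::lm(scores[, j] ~ y)
    summary(fit)$r.squared
  }, numeric(1))
  sum(r2 * eigenvalues[keep]) / sum(eigenvalues[keep])
}

# brute-force gap-split oracle: evaluate every consecutive split with t.test
oracle_gap_split <- function(values, regions) {
  ms <- tapply(values, regions, mean)
  ord <- names(ms)[order(-ms, names(ms))]
  ms <- ms[ord]
  R <- length(ord)
  gaps <- ms[-R] - ms[-1]
  k_star <- which.max(gaps)
  splits <- lapply(seq_len(R - 1), function(k) {
    hi <- ord[seq_len(k)]
    lo <- setdiff(ord, hi)
    t1 <- stats::t.test(values[regions %in% hi], values[regions %in% lo])
    t2 <- stats::t.test(values[regions == ord[k]],
                        values[regions == ord[k + 1]])
    lfc1 <- log2((expm1(mean(values[regions %in% hi])) + 1e-9) /
                   (expm1(mean(values[regions %in% lo])) + 1e-9))
    lfc2 <- log2((expm1(mean(values[regions == ord[k]])) + 1e-9) /
                   (expm1(mean(values[regions == ord[k + 1]])) + 1e-9))
    list(k = k, hi = hi, lo = lo, p_group = t1$p.value,
         p_boundary = t2$p.value, lfc_group = lfc1, lfc_boundary = lfc2)
  })
  best <- splits[[k_star]]
  list(ordered = ord, k_star = unname(k_star), high = best$hi,
       low = best$lo, p_group = best$p_group,
       p_boundary = best$p_boundary, lfc_group = best$lfc_group,
       lfc_boundary = best$lfc_boundary,
       p_final = max(best$p_group, best$p_boundary),
       lfc_final = min(best$lfc_group, best$lfc_boundary))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact LR permutation p by enumerating all distinct two-type label
# assignments (uniform over assignments = uniform over label orderings)
oracle_lr_exact_p <- function(expr, labels, ligand, receptor,
                              sender, receiver) {
  n <- length(labels)
  type_a <- sort(unique(labels))[1]
  n_a <- sum(labels == type_a)
  obs <- interactionScore(expr, labels, ligand, receptor, sender, receiver)$mu
  combos <- utils::combn(n, n_a)
  mus <- apply(combos, 2, function(ix) {
    lab <- rep(sort(unique(labels))[2], n)
    lab[ix] <- type_a
    interactionScore(expr, lab, ligand, receptor, sender, receiver)$mu
  })
  mean(mus >= obs)
}

# plant a niche-restricted ligand-receptor pair: simulate a null cohort,
# pick the two non-marker genes whose baseline expressing fraction is
# closest to `target_frac` (below the LR testability floor, so the pair is
# untestable outside its niche), then re-simulate with the pair elevated in
# one region's sender/receiver types
plant_low_expression_lr <- function(config, region, sender, receiver,
                                    fold = 4, target_frac = 0.05) {
  base <- simulateCohort(config)$cohort
  counts <- SummarizedExperiment::assay(base, "counts")
  frac <- Matrix::rowMeans(counts > 0)
  mk <- markerGenes(config)$gene_id
  cand <- setdiff(rownames(base)[!SummarizedExperiment::rowData(base)$is_mito],
                  mk)
  cand <- cand[frac[cand] > 0]
  window <- cand[frac[cand] >= target_frac - 0.015 &
                   frac[cand] <= target_frac + 0.015]
  if (length(window) >= 2) cand <- window
  cand <- cand[order(abs(frac[cand] - target_frac))]
  lr <- plantedLRPairs(ligand = cand[1], receptor = cand[2],
                       sender_type = sender, receiver_type = receiver,
                       region = region, fold = fold)
  list(sim = simulateCohort(config, lr_pairs = lr), lr = lr)
}

quick_normalize <- function(cohort)
  logNormalize(cohort, computeSizeFactors(cohort,
                                          factor(rep(1, ncol(cohort)))))

# Hand-enumerated QC fixture: 12 cells, 6 genes, thresholds chosen so that
# exactly 4 cells fail (one per filter) and 2 genes fail the support filter.
qc_fixture <- function() {
  set.seed(99)
  counts <- matrix(rpois(12 * 6, 30), nrow = 6)
  counts[, 12] <- c(600, 0, 0, 0, 0, 0)          # extreme depth
  counts[5, ] <- 0
  counts[6, ] <- 0
  counts[5, 1:3] <- 1                            # gene 5: 3 cells  < 4
  counts[6, 1:5] <- 1                            # gene 6: 5 cells >= 4
  counts[1, 2] <- 200                            # mito overload for cell 2
  counts[, 3] <- c(2, 3, 1, 2, 0, 0)             # low depth cell 3
  cells <- make_cell_table(12)
  cells$tissue_class <- c(rep("bone", 8), rep("brain", 4))
  cells$doublet_score[4] <- 0.5                  # doublet cell 4
  genes <- make_gene_table(6)
  genes$is_mito <- c(TRUE, rep(FALSE, 5))
  coh <- MarrowCohort(counts, cells, genes)
  thr <- qcThresholds(mito_max = c(bone = 0.5, brain = 0.6),
                      umi_min = c(bone = 50, brain = 50),
                      umi_max = 500, min_cells_per_gene = 4)
  list(cohort = coh, thr = thr)
}

# independent cell-by-cell enumeration of the filter outcomes
oracle_qc <- function(coh, thr) {
  cd <- as.data.frame(colData(coh))
  counts <- as.matrix(assay(coh, "counts"))
  keep <- rep(TRUE, ncol(coh))
  why <- rep(NA_character_, ncol(coh))
  for (i in seq_len(ncol(coh))) {
    tc <- cd$tissue_class[i]
    if (cd$mito_fraction[i] > thr$mito_max[tc]) why[i] <- "mito"
    else if (cd$total_umi[i] < thr$umi_min[tc]) why[i] <- "umi_min"
    else if (cd$total_umi[i] > thr$umi_max) why[i] <- "umi_max"
    else if (cd$doublet_score[i] > thr$doublet_max) why[i] <- "doublet"
  }
  keep <- is.na(why)
  genes_keep <- rowSums(counts[, keep, drop = FALSE] > 0) >=
    thr$min_cells_per_gene
  list(keep = keep, why = why, genes_keep = genes_keep)
}

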