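#' @importFrom stats pt p.adjust t.test sd
NULL

#' Differential-expression thresholds
#'
#' Defaults are raw `p < 0.05` with log2 fold change above 1; the
#' cross-compartment neutrophil analysis uses the relaxed 0.5 fold bound
#' (`deThresholds(lfc_min = 0.5)`).
#'
#' @param p_max maximum p-value (default 0.05).
#' @param lfc_min minimum log2 fold change (default 1.0).
#' @return a list of class `de_thresholds`.
#' @export
deThresholds <- function(p_max = 0.05, lfc_min = 1.0) {
  stopifnot(p_max > 0, p_max < 1, lfc_min >= 0)
  structure(list(p_max = p_max, lfc_min = lfc_min), class = "de_thresholds")
}

# Welch two-sample t-test from group summary statistics; identical to
# stats::t.test on the raw data. Degenerate zero-variance pairs: equal means
# give (t = 0, p = 1), unequal means (t = +/-Inf, p = 0).
welch_stats <- function(n1, m1, v1, n2, m2, v2) {
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1))
    return(list(t = sign(m1 - m2) * Inf, p = 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# log2 ratio of de-logged (expm1 of mean log-normalized) group means with a
# 1e-9 pseudocount in numerator and denominator
lfc_from_means <- function(m_hi, m_lo)
  log2((expm1(m_hi) + 1e-9) / (expm1(m_lo) + 1e-9))

# core gap-split evaluation from per-region summary statistics
# (region names sorted by descending mean on entry)
gap_split_core <- function(rn, ns, ms, vs, sums, sumsqs) {
  R <- length(rn)
  gaps <- ms[-R] - ms[-1]
  if (all(gaps == 0)) {
    k_star <- 1L
    degenerate <- TRUE
  } else {
    k_star <- which.max(gaps)
    degenerate <- FALSE
  }
  hi <- seq_len(k_star)
  lo <- setdiff(seq_len(R), hi)
  n_h <- sum(ns[hi]); n_l <- sum(ns[lo])
  m_h <- sum(sums[hi]) / n_h; m_l <- sum(sums[lo]) / n_l
  v_h <- (sum(sumsqs[hi]) - n_h * m_h^2) / (n_h - 1)
  v_l <- (sum(sumsqs[lo]) - n_l * m_l^2) / (n_l - 1)
  v_h <- max(v_h, 0); v_l <- max(v_l, 0)
  t1 <- welch_stats(n_h, m_h, v_h, n_l, m_l, v_l)
  b_h <- k_star; b_l <- k_star + 1L
  t2 <- welch_stats(ns[b_h], ms[b_h], vs[b_h], ns[b_l], ms[b_l], vs[b_l])
  lfc_group <- lfc_from_means(m_h, m_l)
  lfc_boundary <- lfc_from_means(ms[b_h], ms[b_l])
  list(ordered_regions = rn, split_index = k_star,
       high_group = rn[hi], low_group = rn[lo],
       p_group = t1$p, p_boundary = t2$p,
       lfc_group = lfc_group, lfc_boundary = lfc_boundary,
       degenerate = degenerate)
}

gap_split_row <- function(gene, cell_type, core, thresholds) {
  p_final <- max(core$p_group, core$p_boundary)
  lfc_final <- min(core$lfc_group, core$lfc_boundary)
  data.frame(
    gene_id = gene, cell_type = cell_type,
    ordered_regions = paste(core$ordered_regions, collapse = ","),
    split_index = as.integer(core$split_index),
    high_group = paste(core$high_group, collapse = ","),
    low_group = paste(core$low_group, collapse = ","),
    p_group = core$p_group, p_boundary = core$p_boundary,
    lfc_group = core$lfc_group, lfc_boundary = core$lfc_boundary,
    p_final = p_final, lfc_final = lfc_final,
    is_deg = p_final < thresholds$p_max & lfc_final > thresholds$lfc_min,
    stringsAsFactors = FALSE)
}

region_gene_stats <- function(lc, regions, min_cells = 2L) {
  tab <- table(regions)
  keep <- names(tab)[tab >= min_cells]
  dropped <- setdiff(names(tab), keep)
  if (length(dropped))
    warning("regions with fewer than ", min_cells, " cells excluded: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2)
    stop("fewer than 2 regions with at least ", min_cells, " cells",
         call. = FALSE)
  ns <- as.integer(tab[keep])
  sums <- vapply(keep, function(r)
    Matrix::rowSums(lc[, regions == r, drop = FALSE]), numeric(nrow(lc)))
  sq <- lc
  if (methods::is(sq, "sparseMatrix")) sq@x <- sq@x^2 else sq <- sq^2
  sumsqs <- vapply(keep, function(r)
    Matrix::rowSums(sq[, regions == r, drop = FALSE]), numeric(nrow(lc)))
  if (nrow(lc) == 1) {
    sums <- matrix(sums, nrow = 1, dimnames = list(rownames(lc), keep))
    sumsqs <- matrix(sumsqs, nrow = 1, dimnames = list(rownames(lc), keep))
  }
  list(regions = keep, ns = ns, sums = sums, sumsqs = sumsqs)
}

#' Gap-split combinatorial differential expression test for one gene
#'
#' Regions are ordered by the gene's mean log-normalized expression and
#' split into a high and a low group at the largest consecutive mean gap
#' (ties resolved toward the smallest split index). Two Welch t-tests are
#' combined: one on all cells of the high vs low groups, one on the two
#' regions flanking the gap, the second ensuring the groups' closest members
#' differ. The reported `p_final` is the maximum of the two p-values and
#' `lfc_final` the minimum of the two log2 fold changes (fold changes are
#' ratios of de-logged group means with a 1e-9 pseudocount). A gene is
#' called differentially expressed when `p_final < p_max` and
#' `lfc_final > lfc_min`.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param gene gene id.
#' @param thresholds a [deThresholds()] list.
#' @param cells optional cell subset (logical or indices).
#' @param region_col colData column holding the region labels.
#' @return a one-row data.frame (see [runCombinatorialDE()] for columns).
#' @export
gapSplitTest <- function(cohort, gene, thresholds = deThresholds(),
                         cells = NULL, region_col = "region") {
  lc <- logcounts_of(cohort)
  if (!gene %in% rownames(cohort))
    stop("gene not in cohort: ", gene, call. = FALSE)
  regions <- as.character(colData(cohort)[[region_col]])
  if (!is.null(cells)) {
    lc <- lc[, cells, drop = FALSE]
    regions <- regions[if (is.logical(cells)) which(cells) else cells]
  }
  st <- region_gene_stats(lc[gene, , drop = FALSE], regions)
  row_for_gene(gene, "all", st, 1L, thresholds)
}

row_for_gene <- function(gene, cell_type, st, g, thresholds) {
  ns <- st$ns
  sums <- st$sums[g, ]
  sumsqs <- st$sumsqs[g, ]
  ms <- sums / ns
  vs <- pmax((sumsqs - ns * ms^2) / (ns - 1), 0)
  ord <- order(-ms, st$regions)
  core <- gap_split_core(st$regions[ord], ns[ord], ms[ord], vs[ord],
                         sums[ord], sumsqs[ord])
  gap_split_row(gene, cell_type, core, thresholds)
}

#' Combinatorial differential expression scan
#'
#' Applies [gapSplitTest()] to every gene, either pooled over all cells or
#' within each cell-type stratum. Rows for all tested genes are retained
#' with their `is_deg` flag; per-region up/down counts can be aggregated
#' with [countDEGs()].
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param thresholds a [deThresholds()] list.
#' @param genes gene subset (default: all genes).
#' @param scope `"pooled"` (default) or `"per_cell_type"`.
#' @param region_col,cell_type_col colData columns.
#' @return a data.frame, one row per gene (x cell type).
#' @export
runCombinatorialDE <- function(cohort, thresholds = deThresholds(),
                               genes = NULL, scope = c("pooled",
                                                       "per_cell_type"),
                               region_col = "region",
                               cell_type_col = "cell_type") {
  scope <- match.arg(scope)
  lc <- logcounts_of(cohort)
  if (is.null(genes)) genes <- rownames(cohort)
  lc <- lc[genes, , drop = FALSE]
  regions <- as.character(colData(cohort)[[region_col]])
  strata <- if (scope == "pooled") list(all = rep(TRUE, ncol(cohort)))
  else {
    ct <- as.character(colData(cohort)[[cell_type_col]])
    stats::setNames(lapply(sort(unique(ct)), function(t) ct == t),
                    sort(unique(ct)))
  }
  out <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    st <- region_gene_stats(lc[, sel, drop = FALSE], regions[sel])
    rows <- lapply(seq_along(genes), function(g)
      row_for_gene(genes[g], s, st, g, thresholds))
    out[[s]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-region DEG direction counts
#'
#' Aggregates a [runCombinatorialDE()] table into per-(cell type, region)
#' counts of genes called up (region in the high group) and down (region in
#' the low group), the bar-plot summary of the combinatorial test.
#'
#' @param de_table a [runCombinatorialDE()] result.
#' @return data.frame with `cell_type`, `region`, `n_up`, `n_down`.
#' @export
countDEGs <- function(de_table) {
  deg <- de_table[de_table$is_deg, , drop = FALSE]
  regs <- sort(unique(unlist(strsplit(
    paste(de_table$high_group, de_table$low_group, sep = ","), ","))))
  grid <- expand.grid(cell_type = unique(de_table$cell_type), region = regs,
                      stringsAsFactors = FALSE)
  grid$n_up <- mapply(function(ct, r) {
    sum(deg$cell_type == ct &
          vapply(strsplit(deg$high_group, ","), function(h) r %in% h,
                 logical(1)))
  }, grid$cell_type, grid$region)
  grid$n_down <- mapply(function(ct, r) {
    sum(deg$cell_type == ct &
          vapply(strsplit(deg$low_group, ","), function(l) r %in% l,
                 logical(1)))
  }, grid$cell_type, grid$region)
  grid
}

#' Per-gene Welch t-tests with Benjamini-Hochberg correction
#'
#' Tests each listed gene between two groups of cells (e.g. CD45+ cells of
#' one bone, naive vs injury) on the log-normalized values and adjusts the
#' p-values by the Benjamini-Hochberg step-up over the tested genes only.
#' Genes absent from the cohort yield an `NA` row with a warning.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param genes character vector of genes to test.
#' @param group two-level vector, one entry per selected cell.
#' @param cells optional cell subset the grouping refers to.
#' @return data.frame: `gene_id`, `group_a`, `group_b`, `t`, `p`, `p_adj`,
#'   `lfc` (group a over group b).
#' @export
groupedTTestBH <- function(cohort, genes, group, cells = NULL) {
  lc <- logcounts_of(cohort)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  group <- as.character(group)
  stopifnot(length(group) == ncol(lc))
  lv <- sort(unique(group))
  if (length(lv) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  a <- group == lv[1]
  if (sum(a) < 2 || sum(!a) < 2)
    stop("both groups need at least 2 cells", call. = FALSE)
  res <- lapply(genes, function(g) {
    if (!g %in% rownames(lc)) {
      warning("gene absent from cohort: ", g)
      return(data.frame(gene_id = g, group_a = lv[1], group_b = lv[2],
                        t = NA_real_, p = NA_real_, p_adj = NA_real_,
                        lfc = NA_real_, stringsAsFactors = FALSE))
    }
    x <- as.numeric(lc[g, a]); y <- as.numeric(lc[g, !a])
    w <- welch_stats(length(x), mean(x), var(x), length(y), mean(y), var(y))
    data.frame(gene_id = g, group_a = lv[1], group_b = lv[2],
               t = w$t, p = w$p, p_adj = NA_real_,
               lfc = lfc_from_means(mean(x), mean(y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p)
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out
}

#' Pro- and anti-inflammatory gene sets
#'
#' The published gene lists, loaded verbatim (including the literal tokens
#' `Il7d` and `Il7f`, which have no standard mouse gene symbol and are kept
#' as printed rather than corrected).
#'
#' @return named list with `pro_inflammatory` and `anti_inflammatory`
#'   character vectors.
#' @export
inflammatoryGeneSets <- function() {
  list(pro_inflammatory = c("Il6", "Il1a", "Il1b", "Ifng", "Il11", "Il7d",
                            "Il7f", "Il18", "Tnf"),
       anti_inflammatory = c("Il1rn", "Tgfb1", "Il4", "Il10", "Il12a",
                             "Il13"))
}

#' Gene-set score per cell with group summaries
#'
#' The per-cell score is the mean log-normalized expression over the set's
#' genes present in the cohort; listed genes absent from the matrix are
#' dropped with a warning, never imputed. Group means and standard
#' deviations are reported per level of `group`.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param set_name label for the set.
#' @param genes character vector of set genes.
#' @param group per-cell grouping vector.
#' @param cells optional cell subset.
#' @return list with `set_name`, `genes_used`, `cell_score` (numeric per
#'   cell), and `summary` (data.frame `group`, `mean`, `sd`, `n`).
#' @export
geneSetScore <- function(cohort, set_name, genes, group, cells = NULL) {
  lc <- logcounts_of(cohort)
  if (!is.null(cells)) {
    lc <- lc[, cells, drop = FALSE]
    group <- group[if (is.logical(cells)) which(cells) else cells]
  }
  present <- intersect(genes, rownames(lc))
  if (!length(present))
    stop("none of the listed genes is present in the cohort", call. = FALSE)
  missing <- setdiff(genes, present)
  if (length(missing))
    warning("set genes absent from cohort: ", paste(missing, collapse = ", "))
  score <- Matrix::colMeans(lc[present, , drop = FALSE])
  group <- as.character(group)
  sm <- do.call(rbind, lapply(sort(unique(group)), function(gv) {
    s <- score[group == gv]
    data.frame(group = gv, mean = mean(s), sd = sd(s), n = length(s),
               stringsAsFactors = FALSE)
  }))
  list(set_name = set_name, genes_used = present,
       cell_score = as.numeric(score), summary = sm)
}

#' Subgroup-relative proportion correlation
#'
#' Transforms single-cell cell-type counts into proportions relative to a
#' parent gate (each type's count divided by the summed counts of all types
#' sharing its parent, per sample), mirroring how flow-cytometry
#' measurements are gated, then reports the Pearson correlation against the
#' reference proportions per sample and their mean.
#'
#' @param sc_counts numeric matrix/data.frame, samples x cell types, of
#'   single-cell counts.
#' @param ref_props matching matrix of reference proportions (same columns).
#' @param parent_map named character vector mapping each cell type to its
#'   parent gate.
#' @return list with `per_sample` (data.frame `sample`, `r`), `mean_r`, and
#'   `transformed` (the relative-proportion matrix; `NA` where a parent gate
#'   had zero cells).
#' @export
proportionCorrelation <- function(sc_counts, ref_props, parent_map) {
  sc <- as.matrix(sc_counts)
  ref <- as.matrix(ref_props)
  types <- colnames(sc)
  stopifnot(!is.null(types), all(types %in% names(parent_map)))
  shared <- intersect(types, colnames(ref))
  if (length(shared) < 2)
    stop("need at least 2 shared cell types", call. = FALSE)
  trans <- sc
  for (tp in types) {
    sibs <- types[parent_map[types] == parent_map[tp]]
    tot <- rowSums(sc[, sibs, drop = FALSE])
    trans[, tp] <- ifelse(tot > 0, sc[, tp] / tot, NA)
  }
  per <- data.frame(sample = rownames(sc), r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sc)))
    per$r[i] <- suppressWarnings(
      cor(trans[i, shared], ref[i, shared], use = "pairwise.complete.obs"))
  list(per_sample = per, mean_r = mean(per$r, na.rm = TRUE),
       transformed = trans)
}
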