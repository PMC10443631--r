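#' Load a ligand-receptor interaction database
#'
#' Reads a TSV with columns `interaction_id`, `ligand`, `receptor` (one
#' representative gene per partner; complexes are expected to be flattened
#' to their minimum-expression member upstream). With no path, the bundled
#' toy database of ~50 mouse pairs is loaded.
#'
#' @param path TSV path, or NULL for the bundled toy database.
#' @return a data.frame with the three columns.
#' @export
lrDatabase <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lr_toy_db.tsv",
                        package = "MarrowDivergence", mustWork = TRUE)
  db <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("interaction_id", "ligand", "receptor")
  miss <- setdiff(need, colnames(db))
  if (length(miss))
    stop("database lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(db$interaction_id))
    stop("interaction ids not unique", call. = FALSE)
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor)))
    stop("empty gene names in database", call. = FALSE)
  db[, need]
}

#' Build an interaction database from a cohort's gene panel
#'
#' Convenience for simulation studies: pairs distinct genes from the cohort
#' into `n_pairs` pseudo ligand-receptor rows. Specific pairs (e.g. planted
#' ones) can be prepended via `include`.
#'
#' @param genes character vector of available gene ids.
#' @param n_pairs random pairs to draw.
#' @param include optional data.frame with `ligand`, `receptor` columns put
#'   at the top of the database.
#' @param seed integer seed.
#' @return a [lrDatabase()]-shaped data.frame.
#' @export
randomLRDatabase <- function(genes, n_pairs = 50L, include = NULL,
                             seed = 1L) {
  pairs <- with_seed(seed, {
    idx <- replicate(n_pairs, sample(length(genes), 2L))
    data.frame(ligand = genes[idx[1, ]], receptor = genes[idx[2, ]],
               stringsAsFactors = FALSE)
  })
  if (!is.null(include))
    pairs <- rbind(include[, c("ligand", "receptor")], pairs)
  pairs <- pairs[!duplicated(paste(pairs$ligand, pairs$receptor)), ,
                 drop = FALSE]
  data.frame(interaction_id = sprintf("ix%03d", seq_len(nrow(pairs))),
             ligand = pairs$ligand, receptor = pairs$receptor,
             stringsAsFactors = FALSE)
}

#' Cell types eligible for cross-region interaction comparison
#'
#' Returns the cell types having at least `min_cells` cells in every listed
#' region, so interactions are only compared where every region supports
#' them.
#'
#' @param cohort a [MarrowCohort-class].
#' @param regions regions to require (default: all regions present).
#' @param min_cells minimum per-region census (default 10).
#' @param type_col,region_col colData columns.
#' @return character vector of eligible cell types.
#' @export
eligibleCellTypes <- function(cohort, regions = NULL, min_cells = 10L,
                              type_col = "cell_type",
                              region_col = "region") {
  rl <- as.character(colData(cohort)[[region_col]])
  tl <- as.character(colData(cohort)[[type_col]])
  if (is.null(regions)) regions <- sort(unique(rl))
  census <- table(tl[rl %in% regions], rl[rl %in% regions])
  census <- census[, regions, drop = FALSE]
  rownames(census)[apply(census >= min_cells, 1, all)]
}

#' Balanced resampling of one region's cells
#'
#' Equalizes the cell-type composition used for the permutation null: types
#' with more than `target_n` cells are downsampled uniformly without
#' replacement, smaller types are upsampled with replacement, and types at
#' exactly `target_n` pass through. The output has `target_n` entries per
#' type.
#'
#' @param type_labels character vector of cell-type labels (one region's
#'   cells).
#' @param cell_types types to include; each must have at least one cell.
#' @param target_n cells per type after balancing (default 400).
#' @param seed integer seed.
#' @return integer indices into `type_labels`, length
#'   `target_n * length(cell_types)`.
#' @export
balancedSample <- function(type_labels, cell_types = NULL, target_n = 400L,
                           seed = 1L) {
  if (is.null(cell_types)) cell_types <- sort(unique(type_labels))
  with_seed(seed, {
    idx <- lapply(cell_types, function(tp) {
      pool <- which(type_labels == tp)
      if (!length(pool))
        stop("cell type '", tp, "' has no cells", call. = FALSE)
      if (length(pool) > target_n) sample(pool, target_n)
      else if (length(pool) < target_n)
        pool[sample.int(length(pool), target_n, replace = TRUE)]
      else pool
    })
    unlist(idx, use.names = FALSE)
  })
}

#' Interaction score of one ligand-receptor pair
#'
#' The observed statistic is the average of the two partner means on
#' log-normalized values:
#' `mu = (mean(ligand over sender cells) + mean(receptor over receiver
#' cells)) / 2`, together with the expressing-cell fractions (count > 0) of
#' each partner. Pairs with either fraction below the floor (default 0.1)
#' are inexpressible and skipped from permutation testing.
#'
#' @param expr genes x cells matrix of log-normalized values (typically the
#'   balanced sample).
#' @param type_labels cell-type label per column of `expr`.
#' @param ligand,receptor gene ids (rows of `expr`).
#' @param sender,receiver cell types.
#' @return list with `mu`, `frac_ligand`, `frac_receptor`.
#' @export
interactionScore <- function(expr, type_labels, ligand, receptor,
                             sender, receiver) {
  for (g in c(ligand, receptor))
    if (!g %in% rownames(expr))
      stop("gene not in matrix: ", g, call. = FALSE)
  s_cells <- type_labels == sender
  r_cells <- type_labels == receiver
  lig <- as.numeric(expr[ligand, ])
  rec <- as.numeric(expr[receptor, ])
  list(mu = (mean(lig[s_cells]) + mean(rec[r_cells])) / 2,
       frac_ligand = mean(lig[s_cells] > 0),
       frac_receptor = mean(rec[r_cells] > 0))
}

# per-type mean and expressing-fraction matrices (types x genes)
type_means <- function(xt, labels) {
  m <- rowsum(xt, labels)
  m / as.integer(table(labels)[rownames(m)])
}

#' Ligand-receptor permutation analysis for one region
#'
#' Balances the region's cells to `target_n` per cell type, evaluates every
#' database pair for every ordered (sender, receiver) cell-type combination,
#' and computes a permutation p-value by shuffling the cell-type labels
#' across the balanced sample: one shared shuffle per permutation is
#' evaluated for all interactions, `k` counts permuted scores `>=` the
#' observed score, `p = k / n_perm`, and only `p = 0` is significant. Pairs
#' whose expressing fraction falls below `min_frac` in either partner are
#' reported but not permutation-tested (`p = NA`). Database rows naming
#' genes absent from the cohort are skipped with a warning.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param db an [lrDatabase()] table.
#' @param region region label to analyze.
#' @param cell_types cell types to include (e.g. from
#'   [eligibleCellTypes()]).
#' @param target_n balanced sample size per type (default 400).
#' @param n_perm permutations (default 1000).
#' @param min_frac expressing-fraction floor (default 0.1).
#' @param seed integer seed.
#' @param type_col,region_col colData columns.
#' @return data.frame with one row per (interaction, sender, receiver).
#' @export
lrRegionAnalysis <- function(cohort, db, region, cell_types,
                             target_n = 400L, n_perm = 1000L,
                             min_frac = 0.1, seed = 1L,
                             type_col = "cell_type",
                             region_col = "region") {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  in_region <- as.character(colData(cohort)[[region_col]]) == region
  labels_all <- as.character(colData(cohort)[[type_col]])[in_region]
  lc <- logcounts_of(cohort)[, in_region, drop = FALSE]
  present <- db$ligand %in% rownames(cohort) &
    db$receptor %in% rownames(cohort)
  if (any(!present))
    warning("skipping ", sum(!present),
            " database rows with genes absent from the cohort")
  db <- db[present, , drop = FALSE]
  if (!nrow(db)) stop("no testable database rows", call. = FALSE)
  bal <- balancedSample(labels_all, cell_types, target_n,
                        seed = stage_seed(seed, paste0("balance_", region)))
  genes <- unique(c(db$ligand, db$receptor))
  xt <- t(as.matrix(lc[genes, bal, drop = FALSE]))   # cells x genes
  labels <- labels_all[bal]
  M <- type_means(xt, labels)
  Fr <- type_means((xt > 0) * 1, labels)
  tuples <- expand.grid(row = seq_len(nrow(db)),
                        sender = cell_types, receiver = cell_types,
                        stringsAsFactors = FALSE)
  li <- match(db$ligand[tuples$row], colnames(M))
  ri <- match(db$receptor[tuples$row], colnames(M))
  si <- match(tuples$sender, rownames(M))
  vi <- match(tuples$receiver, rownames(M))
  mu <- (M[cbind(si, li)] + M[cbind(vi, ri)]) / 2
  fl <- Fr[cbind(si, li)]
  fr <- Fr[cbind(vi, ri)]
  expressible <- fl >= min_frac & fr >= min_frac
  k <- rep(NA_integer_, nrow(tuples))
  if (any(expressible)) {
    k[expressible] <- 0L
    e <- which(expressible)
    with_seed(stage_seed(seed, paste0("perm_", region)), {
      for (p in seq_len(n_perm)) {
        pl <- sample(labels)
        Mp <- type_means(xt, pl)
        mu_p <- (Mp[cbind(si[e], li[e])] + Mp[cbind(vi[e], ri[e])]) / 2
        k[e] <- k[e] + (mu_p >= mu[e])
      }
    })
  }
  data.frame(interaction_id = db$interaction_id[tuples$row],
             ligand = db$ligand[tuples$row],
             receptor = db$receptor[tuples$row],
             sender = tuples$sender, receiver = tuples$receiver,
             region = region, mu = mu,
             frac_ligand = fl, frac_receptor = fr,
             expressible = expressible,
             n_perm = as.integer(n_perm), k = k,
             p = k / n_perm,
             significant = !is.na(k) & k == 0L,
             stringsAsFactors = FALSE)
}

#' Ligand-receptor analysis across regions
#'
#' Runs [lrRegionAnalysis()] for every region (default: all) on the cell
#' types eligible in all of them, with independent region-derived seeds.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param db an [lrDatabase()] table.
#' @param regions regions to analyze (default: all present).
#' @param min_cells eligibility census per region (default 10).
#' @inheritParams lrRegionAnalysis
#' @return the row-bound per-region tables.
#' @export
lrAnalysis <- function(cohort, db, regions = NULL, min_cells = 10L,
                       target_n = 400L, n_perm = 1000L, min_frac = 0.1,
                       seed = 1L, type_col = "cell_type",
                       region_col = "region") {
  if (is.null(regions))
    regions <- sort(unique(as.character(colData(cohort)[[region_col]])))
  types <- eligibleCellTypes(cohort, regions, min_cells, type_col,
                             region_col)
  if (!length(types))
    stop("no cell type has at least ", min_cells, " cells in every region",
         call. = FALSE)
  out <- lapply(regions, function(r)
    lrRegionAnalysis(cohort, db, r, types, target_n, n_perm, min_frac,
                     seed, type_col, region_col))
  do.call(rbind, out)
}

#' Common and region-unique interaction calls
#'
#' An interaction tuple (interaction, sender, receiver) is *common* when it
#' is significant (`p = 0`) in every analyzed region, and *unique* to a
#' region when it is significant there while every other region's p-value
#' exceeds `delta_min` (strictly): the minimum p-value difference against
#' the other regions must be above 0.95 by default. Tuples significant in
#' two or more (but not all) regions are neither. Tuples untested in a
#' region (inexpressible there) are treated as `p = 1` for that region, with
#' a message.
#'
#' @param lr_table an [lrAnalysis()] result covering >= 2 regions.
#' @param delta_min minimum p-value difference in (0, 1), default 0.95.
#' @return list with `common` (data.frame of tuples) and `unique`
#'   (data.frame: tuple, `unique_region`, `delta_p`, `supported`).
#' @export
callCommonAndUnique <- function(lr_table, delta_min = 0.95) {
  if (delta_min <= 0 || delta_min >= 1)
    stop("delta_min must be in (0, 1)", call. = FALSE)
  regions <- sort(unique(lr_table$region))
  if (length(regions) < 2)
    stop("need at least 2 regions", call. = FALSE)
  key <- paste(lr_table$interaction_id, lr_table$sender, lr_table$receiver,
               sep = "|")
  tuples <- unique(data.frame(
    interaction_id = lr_table$interaction_id, sender = lr_table$sender,
    receiver = lr_table$receiver, key = key, stringsAsFactors = FALSE))
  P <- matrix(1, nrow(tuples), length(regions),
              dimnames = list(tuples$key, regions))
  filled <- matrix(FALSE, nrow(tuples), length(regions))
  idx <- cbind(match(key, tuples$key), match(lr_table$region, regions))
  pv <- lr_table$p
  P[idx] <- ifelse(is.na(pv), 1, pv)
  filled[idx] <- !is.na(pv)
  if (any(!filled))
    message(sum(!filled), " tuple-region combinations untested; ",
            "treated as p = 1")
  sig <- P == 0
  n_sig <- rowSums(sig)
  common <- tuples[n_sig == length(regions), c("interaction_id", "sender",
                                               "receiver"), drop = FALSE]
  uniq_rows <- which(n_sig == 1)
  uniq <- do.call(rbind, lapply(uniq_rows, function(i) {
    r <- regions[which(sig[i, ])]
    others <- P[i, setdiff(regions, r)]
    data.frame(interaction_id = tuples$interaction_id[i],
               sender = tuples$sender[i], receiver = tuples$receiver[i],
               unique_region = r, delta_p = min(others),
               supported = all(others > delta_min),
               stringsAsFactors = FALSE)
  }))
  if (is.null(uniq))
    uniq <- data.frame(interaction_id = character(), sender = character(),
                       receiver = character(), unique_region = character(),
                       delta_p = numeric(), supported = logical(),
                       stringsAsFactors = FALSE)
  rownames(common) <- NULL
  list(common = common, unique = uniq)
}
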