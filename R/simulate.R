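#' @importFrom stats rnbinom rlnorm runif rnorm
NULL

# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic stage seed: fold a label into an offset below 2^31.
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 10007 + h) %% 2147483629
}

#' Simulation configuration for synthetic multi-region cohorts
#'
#' Describes a factorial cohort design (regions x conditions, one sample per
#' combination) with coarse cell types, negative-binomial UMI counts over
#' lognormal gene means and lognormal library-size factors, per-type marker
#' genes, a fixed expected mitochondrial read share, and an optional doublet
#' fraction. The seed fully determines the simulated cohort.
#'
#' @slot regions,conditions,cell_types label vectors defining the design.
#' @slot cells_per_sample cells drawn per region-by-condition sample.
#' @slot n_genes,n_mito_genes gene panel size and its mitochondrial subset.
#' @slot baseline_log_mean,baseline_log_sd lognormal parameters of the
#'   per-gene baseline rates.
#' @slot nb_dispersion negative-binomial size parameter (shared by default).
#' @slot dispersion_log_sd if positive, per-gene sizes are lognormal around
#'   `nb_dispersion` with this log-sd; 0 keeps a single shared value.
#' @slot libsize_log_mean,libsize_log_sd lognormal library-size factors.
#' @slot marker_genes_per_type,marker_fold marker-gene block per cell type
#'   and its multiplicative elevation.
#' @slot mito_target_fraction expected mitochondrial read fraction of
#'   singlets (baseline share allocated to mito genes).
#' @slot doublet_fraction share of each sample's cells that are doublets.
#' @slot seed integer seed.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  regions = "character", conditions = "character", cell_types = "character",
  cells_per_sample = "integer", n_genes = "integer", n_mito_genes = "integer",
  baseline_log_mean = "numeric", baseline_log_sd = "numeric",
  nb_dispersion = "numeric", dispersion_log_sd = "numeric",
  libsize_log_mean = "numeric", libsize_log_sd = "numeric",
  marker_genes_per_type = "integer", marker_fold = "numeric",
  mito_target_fraction = "numeric", doublet_fraction = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (!length(object@regions)) msgs <- c(msgs, "at least one region required")
  if (anyDuplicated(c(object@regions)))
    msgs <- c(msgs, "region labels not unique")
  if (object@cells_per_sample < 1) msgs <- c(msgs, "cells_per_sample < 1")
  if (object@n_genes < 1) msgs <- c(msgs, "n_genes < 1")
  if (object@n_mito_genes < 0 || object@n_mito_genes >= object@n_genes)
    msgs <- c(msgs, "n_mito_genes must be in [0, n_genes)")
  if (any(object@nb_dispersion <= 0)) msgs <- c(msgs, "nb_dispersion <= 0")
  if (object@baseline_log_sd < 0 || object@libsize_log_sd < 0 ||
      object@dispersion_log_sd < 0)
    msgs <- c(msgs, "log-sd parameters must be >= 0")
  if (object@marker_fold <= 0) msgs <- c(msgs, "marker_fold <= 0")
  if (object@mito_target_fraction < 0 || object@mito_target_fraction >= 1)
    msgs <- c(msgs, "mito_target_fraction must be in [0, 1)")
  if (object@doublet_fraction < 0 || object@doublet_fraction >= 0.5)
    msgs <- c(msgs, "doublet_fraction must be in [0, 0.5)")
  n_marker <- length(object@cell_types) * object@marker_genes_per_type
  if (n_marker > object@n_genes - object@n_mito_genes)
    msgs <- c(msgs, "marker blocks exceed the non-mitochondrial gene panel")
  if (length(msgs)) msgs else TRUE
})

#' Build a simulation configuration
#'
#' @param regions,conditions,cell_types label vectors; defaults are generic
#'   `region1..n` / `naive` / `type1..n` placeholders.
#' @param cells_per_sample cells per region-by-condition sample (default 300).
#' @param n_genes,n_mito_genes gene panel (default 1000 with 10 mito genes).
#' @param baseline_log_mean,baseline_log_sd lognormal gene-rate parameters
#'   (defaults 0.5 and 1, giving a mean total of roughly 3000 UMI per cell at
#'   1000 genes).
#' @param nb_dispersion NB size parameter (default 2, typical UMI-level
#'   overdispersion).
#' @param dispersion_log_sd per-gene lognormal spread of the size parameter
#'   (default 0: shared value).
#' @param libsize_log_mean,libsize_log_sd library-size lognormal parameters
#'   (defaults 0 and 0.35).
#' @param marker_genes_per_type,marker_fold marker block size and fold
#'   (defaults 20 and 5).
#' @param mito_target_fraction expected singlet mito fraction (default 0.05).
#' @param doublet_fraction doublet share per sample (default 0).
#' @param seed integer seed (default 1).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(regions = paste0("region", 1:6),
                      conditions = "naive",
                      cell_types = "type1",
                      cells_per_sample = 300L,
                      n_genes = 1000L, n_mito_genes = 10L,
                      baseline_log_mean = 0.5, baseline_log_sd = 1,
                      nb_dispersion = 2, dispersion_log_sd = 0,
                      libsize_log_mean = 0, libsize_log_sd = 0.35,
                      marker_genes_per_type = 20L, marker_fold = 5,
                      mito_target_fraction = 0.05,
                      doublet_fraction = 0, seed = 1L) {
  methods::new("SimConfig",
    regions = as.character(regions), conditions = as.character(conditions),
    cell_types = as.character(cell_types),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes), n_mito_genes = as.integer(n_mito_genes),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion, dispersion_log_sd = dispersion_log_sd,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    marker_genes_per_type = as.integer(marker_genes_per_type),
    marker_fold = marker_fold,
    mito_target_fraction = mito_target_fraction,
    doublet_fraction = doublet_fraction, seed = as.integer(seed))
}

#' @describeIn simConfig show a compact summary.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  n_samples <- length(object@regions) * length(object@conditions)
  cat("SimConfig:", length(object@regions), "regions x",
      length(object@conditions), "conditions,",
      length(object@cell_types), "cell types,",
      object@cells_per_sample, "cells/sample (",
      n_samples * object@cells_per_sample, "cells ),",
      object@n_genes, "genes\n")
  invisible(NULL)
})

#' Preset configuration matching the multi-bone stroke study design
#'
#' Six bones (three flat: calvaria, scapula, pelvis; two long: humerus,
#' femur; one irregular: vertebra) plus meninges and brain, three conditions
#' (naive, sham, MCAo), and five coarse immune/hematopoietic cell types
#' (neutrophils, monocytes, B cells, progenitors, erythroid cells).
#'
#' @param cells_per_sample cells per sample (default 200, giving a 4800-cell
#'   cohort over the 24 samples).
#' @param n_genes gene panel size (default 1500).
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @examples
#' cohortDesign()
#' @export
cohortDesign <- function(cells_per_sample = 200L, n_genes = 1500L,
                         seed = 1L) {
  simConfig(
    regions = c("calvaria", "scapula", "humerus", "vertebra", "pelvis",
                "femur", "meninges", "brain"),
    conditions = c("naive", "sham", "mcao"),
    cell_types = c("neutrophil", "monocyte", "b_cell", "progenitor",
                   "erythroid"),
    cells_per_sample = cells_per_sample,
    n_genes = n_genes, n_mito_genes = 15L,
    doublet_fraction = 0.03, seed = seed)
}

#' Planted differential-expression effects
#'
#' Builds the effect table consumed by [simulateCohort()]: each row elevates
#' one gene multiplicatively by `2^log2_fold` in the cells matching
#' `region` / `cell_type` / `condition` (`"all"` matches everything).
#'
#' @param gene_id,region character vectors (recycled to a common length).
#' @param cell_type,condition matching scope, default `"all"`.
#' @param log2_fold numeric log2 fold change.
#' @return a data.frame with one row per effect.
#' @export
plantedEffects <- function(gene_id, region, cell_type = "all",
                           condition = "all", log2_fold = 1) {
  data.frame(gene_id = gene_id, region = region, cell_type = cell_type,
             condition = condition, log2_fold = log2_fold,
             stringsAsFactors = FALSE)
}

#' Planted ligand-receptor elevations
#'
#' Each row elevates the ligand gene in sender-type cells and the receptor
#' gene in receiver-type cells of one region by the multiplicative `fold`.
#'
#' @param ligand,receptor gene ids (must differ row-wise).
#' @param sender_type,receiver_type cell types.
#' @param region region label.
#' @param fold multiplicative elevation (> 0), default 4.
#' @return a data.frame with one row per planted pair.
#' @export
plantedLRPairs <- function(ligand, receptor, sender_type, receiver_type,
                           region, fold = 4) {
  df <- data.frame(ligand = ligand, receptor = receptor,
                   sender_type = sender_type, receiver_type = receiver_type,
                   region = region, fold = fold, stringsAsFactors = FALSE)
  if (any(df$ligand == df$receptor))
    stop("ligand and receptor must differ", call. = FALSE)
  if (any(df$fold <= 0)) stop("fold must be positive", call. = FALSE)
  df
}

sim_gene_table <- function(config) {
  n_mito <- config@n_mito_genes
  ids <- c(if (n_mito) paste0("mt_", seq_len(n_mito)),
           sprintf("g%04d", seq_len(config@n_genes - n_mito)))
  data.frame(gene_id = ids,
             is_mito = seq_len(config@n_genes) <= n_mito,
             stringsAsFactors = FALSE)
}

#' Marker-gene assignment of a configuration
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `gene_id`, `cell_type` listing the marker
#'   block of each type.
#' @export
markerGenes <- function(config) {
  gt <- sim_gene_table(config)
  non_mito <- gt$gene_id[!gt$is_mito]
  k <- config@marker_genes_per_type
  do.call(rbind, lapply(seq_along(config@cell_types), function(t) {
    data.frame(gene_id = non_mito[((t - 1) * k + 1):(t * k)],
               cell_type = config@cell_types[t], stringsAsFactors = FALSE)
  }))
}

#' Simulate a multi-region cohort with planted ground truth
#'
#' Draws one sample per region-by-condition combination with
#' `cells_per_sample` cells of uniformly mixed cell types. Counts for cell
#' *i*, gene *g* are negative binomial with mean
#' `libsize_i * mu_g * marker_mult * 2^(sum of applicable planted log2 folds)
#' * lr_mult` and size `nb_dispersion`. Gene baselines `mu_g` are lognormal;
#' mitochondrial genes are rescaled so singlets expect a
#' `mito_target_fraction` mitochondrial read share. A `doublet_fraction` of
#' each sample's cells are sums of two independently drawn singlet profiles
#' and receive doublet scores above 0.1; singlets score below 0.1. The
#' configuration seed makes the output bit-identical across runs.
#'
#' @param config a [SimConfig-class].
#' @param effects optional [plantedEffects()] table; gene ids must exist.
#' @param lr_pairs optional [plantedLRPairs()] table; gene ids must exist.
#' @return a list with elements `cohort` ([MarrowCohort-class]) and `truth`
#'   (list: `planted_effects`, `planted_lr`, `true_cell_type`,
#'   `true_doublet`).
#' @export
simulateCohort <- function(config, effects = NULL, lr_pairs = NULL) {
  methods::validObject(config)
  gt <- sim_gene_table(config)
  if (!is.null(effects) && nrow(effects)) {
    bad <- setdiff(effects$gene_id, gt$gene_id)
    if (length(bad))
      stop("planted effect genes not in cohort: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(lr_pairs) && nrow(lr_pairs)) {
    bad <- setdiff(c(lr_pairs$ligand, lr_pairs$receptor), gt$gene_id)
    if (length(bad))
      stop("planted LR genes not in cohort: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(config@seed, sim_draw(config, gt, effects, lr_pairs))
}

sim_draw <- function(config, gt, effects, lr_pairs) {
  n_genes <- config@n_genes
  mu_g <- rlnorm(n_genes, config@baseline_log_mean, config@baseline_log_sd)
  # allocate the mito genes a fixed share of total expression
  mito <- gt$is_mito
  if (any(mito)) {
    f <- config@mito_target_fraction
    mu_g[mito] <- mu_g[mito] *
      (f / (1 - f)) * sum(mu_g[!mito]) / sum(mu_g[mito])
  }
  size_g <- if (config@dispersion_log_sd > 0)
    rlnorm(n_genes, log(config@nb_dispersion), config@dispersion_log_sd)
  else rep(config@nb_dispersion, n_genes)

  marker_idx <- lapply(seq_along(config@cell_types), function(t) {
    k <- config@marker_genes_per_type
    which(!mito)[((t - 1) * k + 1):(t * k)]
  })
  names(marker_idx) <- config@cell_types

  samples <- expand.grid(region = config@regions,
                         condition = config@conditions,
                         stringsAsFactors = FALSE)
  n <- config@cells_per_sample
  n_types <- length(config@cell_types)

  blocks <- vector("list", nrow(samples))
  cell_rows <- vector("list", nrow(samples))
  true_doublet <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    region <- samples$region[s]
    condition <- samples$condition[s]
    types <- sample(config@cell_types, n, replace = TRUE)
    lib <- rlnorm(n, config@libsize_log_mean, config@libsize_log_sd)
    mult <- sim_multipliers(config, gt, marker_idx, types, region, condition,
                            effects, lr_pairs)
    mu <- (mu_g * mult) * rep(lib, each = n_genes)
    cnt <- matrix(rnbinom(n_genes * n, size = size_g, mu = as.vector(mu)),
                  nrow = n_genes)
    n_d <- round(config@doublet_fraction * n)
    is_dbl <- rep(FALSE, n)
    if (n_d > 0) {
      dbl <- sample(n, n_d)
      is_dbl[dbl] <- TRUE
      # partner profiles drawn fresh from the same sample's generative mix
      ptypes <- sample(config@cell_types, n_d, replace = TRUE)
      plib <- rlnorm(n_d, config@libsize_log_mean, config@libsize_log_sd)
      pmult <- sim_multipliers(config, gt, marker_idx, ptypes, region,
                               condition, effects, lr_pairs)
      pmu <- (mu_g * pmult) * rep(plib, each = n_genes)
      pcnt <- matrix(rnbinom(n_genes * n_d, size = size_g,
                             mu = as.vector(pmu)), nrow = n_genes)
      cnt[, dbl] <- cnt[, dbl, drop = FALSE] + pcnt
    }
    score <- runif(n, 0, 0.0999)
    if (n_d > 0) score[is_dbl] <- runif(n_d, 0.1001, 1)
    blocks[[s]] <- cnt
    tc <- if (region == "meninges") "meninges"
          else if (region == "brain") "brain" else "bone"
    cell_rows[[s]] <- data.frame(
      cell_id = sprintf("%s_%s_c%04d", region, condition, seq_len(n)),
      region = region, condition = condition, cell_type = types,
      sample_id = paste(region, condition, sep = "_"),
      tissue_class = tc, doublet_score = score, stringsAsFactors = FALSE)
    true_doublet[[s]] <- is_dbl
  }
  counts <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
  cells <- do.call(rbind, cell_rows)
  cohort <- MarrowCohort(counts, cells, gt)
  truth <- list(
    planted_effects = if (is.null(effects))
      data.frame(gene_id = character(), region = character(),
                 cell_type = character(), condition = character(),
                 log2_fold = numeric()) else effects,
    planted_lr = if (is.null(lr_pairs))
      data.frame(ligand = character(), receptor = character(),
                 sender_type = character(), receiver_type = character(),
                 region = character(), fold = numeric()) else lr_pairs,
    true_cell_type = cells$cell_type,
    true_doublet = unlist(true_doublet, use.names = FALSE))
  list(cohort = cohort, truth = truth)
}

# genes x cells multiplier matrix for one sample
sim_multipliers <- function(config, gt, marker_idx, types, region, condition,
                            effects, lr_pairs) {
  n_genes <- config@n_genes
  mult <- matrix(1, n_genes, length(types))
  for (t in unique(types))
    mult[marker_idx[[t]], types == t] <- config@marker_fold
  if (!is.null(effects) && nrow(effects)) {
    for (e in seq_len(nrow(effects))) {
      if (effects$region[e] != "all" && effects$region[e] != region) next
      if (effects$condition[e] != "all" &&
          effects$condition[e] != condition) next
      cells_hit <- if (effects$cell_type[e] == "all") seq_along(types)
                   else which(types == effects$cell_type[e])
      if (!length(cells_hit)) next
      g <- match(effects$gene_id[e], gt$gene_id)
      mult[g, cells_hit] <- mult[g, cells_hit] * 2^effects$log2_fold[e]
    }
  }
  if (!is.null(lr_pairs) && nrow(lr_pairs)) {
    for (e in seq_len(nrow(lr_pairs))) {
      if (lr_pairs$region[e] != region) next
      gl <- match(lr_pairs$ligand[e], gt$gene_id)
      gr <- match(lr_pairs$receptor[e], gt$gene_id)
      snd <- which(types == lr_pairs$sender_type[e])
      rcv <- which(types == lr_pairs$receiver_type[e])
      if (length(snd)) mult[gl, snd] <- mult[gl, snd] * lr_pairs$fold[e]
      if (length(rcv)) mult[gr, rcv] <- mult[gr, rcv] * lr_pairs$fold[e]
    }
  }
  mult
}

#' Simulate a null cohort (no planted structure)
#'
#' [simulateCohort()] with empty effect and LR tables; the ground truth
#' records the emptiness. Used to calibrate the permutation tests.
#'
#' @param config a [SimConfig-class].
#' @return as [simulateCohort()].
#' @export
nullCohort <- function(config) simulateCohort(config, NULL, NULL)

#' Append synthetic doublets to a cohort
#'
#' Adds `round(fraction * ncol(cohort))` doublets, each the column sum of two
#' distinct randomly chosen original cells, annotated from the first parent
#' and given a doublet score in (0.1, 1]. Original cells are untouched, so
#' the standard quality-control filter at threshold 0.1 removes exactly the
#' appended cells.
#'
#' @param cohort a [MarrowCohort-class].
#' @param fraction doublet fraction in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a [MarrowCohort-class] with the doublets appended.
#' @export
spikeDoublets <- function(cohort, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 0.5)
    stop("fraction must be in [0, 0.5)", call. = FALSE)
  n_add <- round(fraction * ncol(cohort))
  if (n_add == 0) return(cohort)
  with_seed(seed, {
    counts <- assay(cohort, "counts")
    a <- sample(ncol(cohort), n_add, replace = TRUE)
    b <- vapply(a, function(i) sample(setdiff(seq_len(ncol(cohort)), i), 1L),
                integer(1))
    new_counts <- counts[, a, drop = FALSE] + counts[, b, drop = FALSE]
    cd <- as.data.frame(colData(cohort))
    add <- cd[a, , drop = FALSE]
    add$cell_id <- sprintf("doublet_%04d", seq_len(n_add))
    add$doublet_score <- runif(n_add, 0.1001, 1)
    all_cells <- rbind(cd, add)
    MarrowCohort(cbind(counts, new_counts), all_cells,
                 as.data.frame(rowData(cohort)))
  })
}
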