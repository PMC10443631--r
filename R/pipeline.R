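#' Pipeline run configuration
#'
#' Collects every stage's parameters with their standard defaults (the QC
#' thresholds, 50 principal components, 1000 permutations, 400-cell
#' balancing, 0.95 uniqueness margin, p < 0.05 / LFC > 1 DE thresholds) plus
#' stage toggles, paths and a single global seed. The global seed is
#' expanded into independent per-stage streams by hashing the stage name, so
#' toggling one stage never perturbs another stage's randomness.
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param stages stages to run, subset of
#'   `c("simulate", "qc", "normalize", "divergence", "de", "lr",
#'   "dendrogram")`.
#' @param input_dir cohort directory (read with [readCohort()]) when the
#'   simulate stage is off.
#' @param sim_config a [SimConfig-class] for the simulate stage (default
#'   [cohortDesign()]).
#' @param effects,lr_pairs planted-truth tables for the simulate stage.
#' @param qc a [qcThresholds()] list.
#' @param de a [deThresholds()] list.
#' @param n_hvgs genes kept per sample for HVG selection (default 1000 at
#'   simulation scale; use 4000 for full-size cohorts).
#' @param n_components principal components (default 50).
#' @param n_perm permutations for divergence and LR tests (default 1000).
#' @param lr_db optional [lrDatabase()] table; by default a database is
#'   drawn from the cohort's gene panel.
#' @param lr_target_n,lr_min_frac,lr_min_cells,lr_delta_min LR parameters
#'   (defaults 400, 0.1, 10, 0.95).
#' @param min_cells_divergence minimum group size for divergence (20).
#' @return a list of class `run_config`.
#' @export
runConfig <- function(out_dir, seed = 1L,
                      stages = c("simulate", "qc", "normalize", "divergence",
                                 "de", "lr", "dendrogram"),
                      input_dir = NULL,
                      sim_config = cohortDesign(seed = seed),
                      effects = NULL, lr_pairs = NULL,
                      qc = qcThresholds(), de = deThresholds(),
                      n_hvgs = 1000L, n_components = 50L, n_perm = 1000L,
                      lr_db = NULL, lr_target_n = 400L, lr_min_frac = 0.1,
                      lr_min_cells = 10L, lr_delta_min = 0.95,
                      min_cells_divergence = 20L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, input_dir = input_dir,
                 sim_config = sim_config, effects = effects,
                 lr_pairs = lr_pairs, qc = qc, de = de,
                 n_hvgs = as.integer(n_hvgs),
                 n_components = as.integer(n_components),
                 n_perm = as.integer(n_perm), lr_db = lr_db,
                 lr_target_n = as.integer(lr_target_n),
                 lr_min_frac = lr_min_frac,
                 lr_min_cells = as.integer(lr_min_cells),
                 lr_delta_min = lr_delta_min,
                 min_cells_divergence = as.integer(min_cells_divergence)),
            class = "run_config")
}

pipe_log <- function(con, stage, level, msg) {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg)
  writeLines(line, con)
  message("[", stage, "] ", msg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate or load, quality control,
#' normalization + HVG selection, per-cell-type divergence scan, combinatorial
#' differential expression, ligand-receptor permutation analysis with
#' common/unique calls, region dendrogram), writing each result as a
#' deterministic TSV plus a manifest of output files with MD5 checksums and
#' generating stage. Identical configuration and seed give byte-identical
#' result tables. A stage failure aborts the run with the stage name in the
#' error.
#'
#' @param config a [runConfig()] list.
#' @return invisibly, the manifest data.frame.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  manifest <- data.frame(file = character(), md5 = character(),
                         stage = character(), stringsAsFactors = FALSE)
  emit <- function(df, name, key, stage) {
    path <- file.path(out, name)
    writeResultTable(df, path, key = key)
    manifest[nrow(manifest) + 1L, ] <<-
      list(name, unname(tools::md5sum(path)), stage)
    pipe_log(con, stage, "INFO", paste("wrote", name))
  }
  run_stage <- function(stage, expr) {
    pipe_log(con, stage, "INFO", "start")
    tryCatch(expr, error = function(e) {
      pipe_log(con, stage, "ERROR", conditionMessage(e))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- NULL
  truth <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      sc <- config$sim_config
      sc@seed <- as.integer(stage_seed(config$seed, "simulate"))
      sim <- simulateCohort(sc, config$effects, config$lr_pairs)
      cohort <- sim$cohort
      truth <- sim$truth
      writeCohort(cohort, file.path(out, "cohort"))
    })
  } else {
    run_stage("load", {
      d <- config$input_dir
      cohort <- readCohort(file.path(d, "counts.mtx"),
                            file.path(d, "cells.tsv"),
                            file.path(d, "genes.tsv"))
    })
  }

  if ("qc" %in% config$stages) {
    run_stage("qc", {
      res <- applyQC(cohort, config$qc)
      cohort <- res$cohort
      rep <- res$report
      rep$cells_in <- attr(rep, "cells_in")
      rep$cells_out <- attr(rep, "cells_out")
      emit(rep, "qc_report.tsv", key = "filter", stage = "qc")
    })
  }

  hvg_genes <- NULL
  if ("normalize" %in% config$stages) {
    run_stage("normalize", {
      cl <- clusterForSizeFactors(cohort,
                                  seed = stage_seed(config$seed,
                                                    "normalize"))
      sf <- computeSizeFactors(cohort, cl)
      cohort <- logNormalize(cohort, sf)
      hv <- selectHVGs(cohort, n_per_sample = config$n_hvgs)
      hvg_genes <- hv$combined$gene_id
      emit(hv$combined, "hvg_combined.tsv", key = "gene_id",
           stage = "normalize")
      emit(data.frame(cell_id = colnames(cohort),
                      size_factor = sf, cluster = as.integer(cl)),
           "size_factors.tsv", key = "cell_id", stage = "normalize")
    })
  }

  if ("divergence" %in% config$stages) {
    run_stage("divergence", {
      types <- sort(unique(cellTypeLabels(cohort)))
      tabs <- lapply(types, function(tp) {
        tryCatch(
          divergenceScan(cohort, cell_type = tp, genes = hvg_genes,
                         n_perm = config$n_perm,
                         min_cells = config$min_cells_divergence,
                         n_components = config$n_components,
                         seed = stage_seed(config$seed,
                                           paste0("divergence_", tp))),
          error = function(e) NULL)
      })
      emit(do.call(rbind, tabs), "divergence.tsv",
           key = c("cell_type", "region"), stage = "divergence")
    })
  }

  if ("de" %in% config$stages) {
    run_stage("de", {
      de <- runCombinatorialDE(cohort, config$de)
      emit(de, "combinatorial_de.tsv", key = c("cell_type", "gene_id"),
           stage = "de")
      emit(countDEGs(de), "deg_counts.tsv", key = c("cell_type", "region"),
           stage = "de")
    })
  }

  if ("lr" %in% config$stages) {
    run_stage("lr", {
      db <- config$lr_db
      if (is.null(db))
        db <- randomLRDatabase(rownames(cohort), n_pairs = 50L,
                               seed = stage_seed(config$seed, "lr_db"))
      lr <- lrAnalysis(cohort, db, min_cells = config$lr_min_cells,
                       target_n = config$lr_target_n,
                       n_perm = config$n_perm,
                       min_frac = config$lr_min_frac,
                       seed = stage_seed(config$seed, "lr"))
      emit(lr, "lr_interactions.tsv",
           key = c("region", "interaction_id", "sender", "receiver"),
           stage = "lr")
      calls <- callCommonAndUnique(lr, config$lr_delta_min)
      emit(calls$common, "lr_common.tsv",
           key = c("interaction_id", "sender", "receiver"), stage = "lr")
      emit(calls$unique, "lr_unique.tsv",
           key = c("interaction_id", "sender", "receiver"), stage = "lr")
    })
  }

  if ("dendrogram" %in% config$stages) {
    run_stage("dendrogram", {
      pca <- computePCA(cohort, genes = hvg_genes,
                        n_components = config$n_components)
      den <- regionDendrogram(pca, regionLabels(cohort))
      writeLines(den$newick, file.path(out, "dendrogram.nwk"))
      manifest[nrow(manifest) + 1L, ] <-
        list("dendrogram.nwk",
             unname(tools::md5sum(file.path(out, "dendrogram.nwk"))),
             "dendrogram")
      cm <- data.frame(region = rownames(den$cor_matrix),
                       den$cor_matrix, check.names = FALSE)
      emit(cm, "region_correlation.tsv", key = "region",
           stage = "dendrogram")
    })
  }

  writeResultTable(manifest, file.path(out, "manifest.tsv"), key = "file")
  pipe_log(con, "pipeline", "INFO", "done")
  invisible(manifest)
}
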