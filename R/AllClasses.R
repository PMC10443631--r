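#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
#'   colData<- rowData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

REQUIRED_CELL_COLS <- c("cell_id", "region", "condition", "cell_type",
                        "sample_id", "tissue_class", "total_umi",
                        "mito_fraction", "doublet_score")
REQUIRED_GENE_COLS <- c("gene_id", "is_mito")
TISSUE_CLASSES <- c("bone", "meninges", "brain")
CONDITIONS <- c("naive", "sham", "mcao")

#' Multi-region single-cell cohort container
#'
#' `MarrowCohort` extends [SingleCellExperiment::SingleCellExperiment] and
#' holds a genes-by-cells UMI count matrix (`counts` assay) together with the
#' per-cell annotations every downstream statistic consumes: anatomical
#' `region`, injury `condition` (`naive`/`sham`/`mcao`), `cell_type`,
#' `sample_id`, `tissue_class` (`bone`/`meninges`/`brain`), and the derived
#' `total_umi` and `mito_fraction` plus an externally supplied
#' `doublet_score`. Per-gene annotations carry `gene_id` and the
#' mitochondrial flag `is_mito`.
#'
#' Validity enforces: non-negative integer counts with no missing values,
#' unique cell and gene ids, `total_umi` equal to the column sums, and
#' `mito_fraction` equal to the mitochondrial share of each cell's counts
#' (0 for empty cells). The constructor [MarrowCohort()] recomputes the two
#' derived columns rather than trusting its inputs.
#'
#' @aliases MarrowCohort-class
#' @exportClass MarrowCohort
setClass("MarrowCohort", contains = "SingleCellExperiment")

.check_counts <- function(m) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (anyNA(x)) return("counts contain missing values")
  if (any(x < 0)) return("counts contain negative values")
  if (any(x != round(x))) return("counts contain non-integer values")
  NULL
}

setValidity("MarrowCohort", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cm <- assay(object, "counts")
  bad <- .check_counts(cm)
  if (!is.null(bad)) msgs <- c(msgs, bad)
  cd <- colData(object)
  rd <- rowData(object)
  miss_c <- setdiff(REQUIRED_CELL_COLS, colnames(cd))
  if (length(miss_c))
    msgs <- c(msgs, paste0("missing cell columns: ",
                           paste(miss_c, collapse = ", ")))
  miss_g <- setdiff(REQUIRED_GENE_COLS, colnames(rd))
  if (length(miss_g))
    msgs <- c(msgs, paste0("missing gene columns: ",
                           paste(miss_g, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(cd$cell_id)) msgs <- c(msgs, "cell ids not unique")
    if (anyDuplicated(rd$gene_id)) msgs <- c(msgs, "gene ids not unique")
    tot <- Matrix::colSums(cm)
    if (!isTRUE(all.equal(as.numeric(cd$total_umi), as.numeric(tot),
                          tolerance = 1e-8)))
      msgs <- c(msgs, "total_umi does not equal column sums of counts")
    mito <- as.logical(rd$is_mito)
    mf <- rep(0, ncol(cm))
    nz <- tot > 0
    if (any(mito)) {
      ms <- Matrix::colSums(cm[mito, , drop = FALSE])
      mf[nz] <- ms[nz] / tot[nz]
    }
    if (!isTRUE(all.equal(as.numeric(cd$mito_fraction), mf,
                          tolerance = 1e-8)))
      msgs <- c(msgs, "mito_fraction inconsistent with counts")
    if (any(cd$mito_fraction < 0 | cd$mito_fraction > 1))
      msgs <- c(msgs, "mito_fraction outside [0, 1]")
    if (any(cd$doublet_score < 0 | cd$doublet_score > 1))
      msgs <- c(msgs, "doublet_score outside [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarrowCohort
#'
#' Builds a validated [MarrowCohort-class] from a genes-by-cells count matrix
#' and the two annotation tables. `total_umi` and `mito_fraction` are always
#' recomputed from the counts; values present in `cell_data` are ignored.
#'
#' @param counts genes-by-cells matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse).
#' @param cell_data data.frame with one row per cell: `cell_id`, `region`,
#'   `condition`, `cell_type`, `sample_id`, `tissue_class`, `doublet_score`.
#' @param gene_data data.frame with one row per gene: `gene_id`, `is_mito`.
#' @return a validated `MarrowCohort`.
#' @examples
#' counts <- matrix(rpois(12, 2), nrow = 3,
#'                  dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cells <- data.frame(cell_id = paste0("c", 1:4), region = "calvaria",
#'                     condition = "naive", cell_type = "neutrophil",
#'                     sample_id = "s1", tissue_class = "bone",
#'                     doublet_score = 0)
#' genes <- data.frame(gene_id = paste0("g", 1:3),
#'                     is_mito = c(FALSE, FALSE, TRUE))
#' coh <- MarrowCohort(counts, cells, genes)
#' @export
MarrowCohort <- function(counts, cell_data, gene_data) {
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) != nrow(cell_data))
    stop("dimension mismatch on the cell axis: matrix has ", ncol(counts),
         " cells but cell table has ", nrow(cell_data), " rows",
         call. = FALSE)
  if (nrow(counts) != nrow(gene_data))
    stop("dimension mismatch on the gene axis: matrix has ", nrow(counts),
         " genes but gene table has ", nrow(gene_data), " rows",
         call. = FALSE)
  bad <- .check_counts(counts)
  if (!is.null(bad)) stop(bad, call. = FALSE)
  cell_data <- as.data.frame(cell_data)
  gene_data <- as.data.frame(gene_data)
  for (col in setdiff(REQUIRED_CELL_COLS,
                      c(colnames(cell_data), "total_umi", "mito_fraction")))
    stop("cell table lacks required column '", col, "'", call. = FALSE)
  for (col in setdiff(REQUIRED_GENE_COLS, colnames(gene_data)))
    stop("gene table lacks required column '", col, "'", call. = FALSE)
  gene_data$is_mito <- as.logical(gene_data$is_mito)
  tot <- Matrix::colSums(counts)
  mito <- gene_data$is_mito
  mf <- rep(0, ncol(counts))
  if (any(mito)) {
    ms <- Matrix::colSums(counts[mito, , drop = FALSE])
    mf[tot > 0] <- ms[tot > 0] / tot[tot > 0]
  }
  cell_data$total_umi <- as.integer(round(tot))
  cell_data$mito_fraction <- mf
  dimnames(counts) <- list(gene_data$gene_id, cell_data$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_data[, REQUIRED_CELL_COLS, drop = FALSE],
                        row.names = cell_data$cell_id),
    rowData = DataFrame(gene_data[, REQUIRED_GENE_COLS, drop = FALSE],
                        row.names = gene_data$gene_id))
  methods::validObject(out <- methods::new("MarrowCohort", sce))
  out
}

#' @describeIn MarrowCohort show a compact summary.
#' @param object a `MarrowCohort`.
#' @export
setMethod("show", "MarrowCohort", function(object) {
  cat("MarrowCohort:", nrow(object), "genes x", ncol(object), "cells\n")
  cd <- colData(object)
  if (ncol(object)) {
    cat("  regions:   ", paste(sort(unique(as.character(cd$region))),
                               collapse = ", "), "\n")
    cat("  conditions:", paste(sort(unique(as.character(cd$condition))),
                               collapse = ", "), "\n")
    cat("  cell types:", paste(sort(unique(as.character(cd$cell_type))),
                               collapse = ", "), "\n")
    cat("  assays:    ", paste(assayNames(object), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Accessors for MarrowCohort annotation columns
#'
#' Convenience getters for the per-cell annotation columns used throughout
#' the analysis; each returns a plain character (or numeric) vector of
#' length `ncol(x)`.
#'
#' @param x a [MarrowCohort-class].
#' @return a vector of per-cell values.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
regionLabels <- function(x) as.character(colData(x)$region)

#' @rdname cohort-accessors
#' @export
conditionLabels <- function(x) as.character(colData(x)$condition)

#' @rdname cohort-accessors
#' @export
cellTypeLabels <- function(x) as.character(colData(x)$cell_type)

#' @rdname cohort-accessors
#' @export
sampleLabels <- function(x) as.character(colData(x)$sample_id)

#' Principal component decomposition of a normalized layer
#'
#' Holds the exact singular-value decomposition of the centered
#' cells-by-genes log-normalized matrix restricted to a gene subset:
#' per-cell component `scores`, per-component explained variances
#' (`eigenvalues`, the lambda_j weighting the divergence score), and the
#' orthonormal gene `loadings`. Component signs are fixed so that the
#' largest-magnitude loading of each component is positive, making the
#' decomposition deterministic.
#'
#' @slot scores cells-by-K matrix of component scores.
#' @slot eigenvalues length-K non-increasing vector, singular_value^2/(n-1).
#' @slot loadings genes-by-K orthonormal matrix.
#' @slot genes character vector of the genes used.
#' @aliases CohortPCA-class
#' @exportClass CohortPCA
setClass("CohortPCA",
         representation(scores = "matrix", eigenvalues = "numeric",
                        loadings = "matrix", genes = "character"))

setValidity("CohortPCA", function(object) {
  k <- length(object@eigenvalues)
  msgs <- character()
  if (ncol(object@scores) != k || ncol(object@loadings) != k)
    msgs <- c(msgs, "component count mismatch between slots")
  if (any(object@eigenvalues < -1e-10))
    msgs <- c(msgs, "negative eigenvalue")
  if (k > 1 && any(diff(object@eigenvalues) > 1e-8))
    msgs <- c(msgs, "eigenvalues not sorted non-increasing")
  if (nrow(object@loadings) != length(object@genes))
    msgs <- c(msgs, "loadings rows do not match gene subset")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CohortPCA show a compact summary.
#' @param object a `CohortPCA`.
#' @export
setMethod("show", "CohortPCA", function(object) {
  cat("CohortPCA:", nrow(object@scores), "cells,",
      length(object@eigenvalues), "components\n")
  tv <- sum(object@eigenvalues)
  if (tv > 0)
    cat("  top component explains ",
        sprintf("%.1f%%", 100 * object@eigenvalues[1] / tv),
        " of retained variance\n", sep = "")
  invisible(NULL)
})

#' @rdname CohortPCA-class
#' @param x a `CohortPCA`.
#' @export
pcaScores <- function(x) x@scores

#' @rdname CohortPCA-class
#' @export
pcaEigenvalues <- function(x) x@eigenvalues

#' @rdname CohortPCA-class
#' @export
pcaLoadings <- function(x) x@loadings
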