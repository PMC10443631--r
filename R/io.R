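#' @importFrom utils read.delim write.table
NULL

ORIENT_FLAG <- "# orientation:"

#' Read a cohort from Matrix Market + TSV sidecars
#'
#' Reads a UMI count matrix in Matrix Market coordinate format together with
#' the per-cell and per-gene annotation sidecars (tab-separated, header row)
#' and returns a validated [MarrowCohort-class]. The cells sidecar may start
#' with a comment line `# orientation: genes_x_cells` (the default written by
#' [writeCohort()]) or `# orientation: cells_x_genes`; the matrix is
#' transposed as needed so that genes end up on rows internally. Derived
#' per-cell fields (`total_umi`, `mito_fraction`) are recomputed from the
#' counts, never trusted from the sidecar.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param cells_path path to the per-cell TSV.
#' @param genes_path path to the per-gene TSV.
#' @return a [MarrowCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(matrix_path, cells_path, genes_path) {
  for (p in c(matrix_path, cells_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  m <- Matrix::readMM(matrix_path)
  first <- readLines(cells_path, n = 1L)
  orientation <- "genes_x_cells"
  skip <- 0L
  if (startsWith(first, ORIENT_FLAG)) {
    orientation <- trimws(sub(ORIENT_FLAG, "", first, fixed = TRUE))
    skip <- 1L
  }
  if (!orientation %in% c("genes_x_cells", "cells_x_genes"))
    stop("unknown orientation flag '", orientation, "'", call. = FALSE)
  cells <- read.delim(cells_path, sep = "\t", skip = skip,
                      stringsAsFactors = FALSE, check.names = FALSE)
  genes <- read.delim(genes_path, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  if (orientation == "cells_x_genes") m <- Matrix::t(m)
  if (nrow(m) != nrow(genes))
    stop("dimension mismatch on the gene axis: matrix has ", nrow(m),
         " genes but gene sidecar has ", nrow(genes), " rows",
         call. = FALSE)
  if (ncol(m) != nrow(cells))
    stop("dimension mismatch on the cell axis: matrix has ", ncol(m),
         " cells but cell sidecar has ", nrow(cells), " rows",
         call. = FALSE)
  MarrowCohort(m, cells, genes)
}

#' Write a cohort to Matrix Market + TSV sidecars
#'
#' Writes `counts.mtx` (genes x cells, coordinate integer format),
#' `cells.tsv` (with a leading `# orientation: genes_x_cells` flag) and
#' `genes.tsv` into `out_dir`, and returns a manifest listing each file with
#' its MD5 checksum and dimensions. Round-trips losslessly through
#' [readCohort()].
#'
#' @param cohort a [MarrowCohort-class].
#' @param out_dir output directory, created if absent.
#' @return invisibly, a data.frame manifest with columns `file`, `md5`,
#'   `nrow`, `ncol`.
#' @export
writeCohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  mtx <- file.path(out_dir, "counts.mtx")
  cpath <- file.path(out_dir, "cells.tsv")
  gpath <- file.path(out_dir, "genes.tsv")
  m <- methods::as(assay(cohort, "counts"), "CsparseMatrix")
  # writeMM emits a real-valued header for dgCMatrix; rewrite as integer
  Matrix::writeMM(m, mtx)
  cd <- as.data.frame(colData(cohort))
  gd <- as.data.frame(rowData(cohort))
  # full-precision doubles so annotations survive the round trip bit-exactly
  for (j in seq_along(cd))
    if (is.double(cd[[j]])) cd[[j]] <- sprintf("%.17g", cd[[j]])
  con <- file(cpath, "w")
  writeLines(paste(ORIENT_FLAG, "genes_x_cells"), con)
  write.table(cd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write.table(gd, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(mtx, cpath, gpath)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    nrow = c(nrow(m), nrow(cd), nrow(gd)),
    ncol = c(ncol(m), ncol(cd), ncol(gd)),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a result table as deterministic TSV
#'
#' Emits a tab-separated file with a header row, floats rendered with 12
#' significant digits, `NA` for missing values, and rows sorted by the given
#' key columns so repeated runs are byte-identical.
#'
#' @param table a data.frame.
#' @param out_path destination path.
#' @param key character vector of key column names used for sorting;
#'   duplicated key combinations are an error.
#' @return invisibly, `out_path`.
#' @export
writeResultTable <- function(table, out_path, key = NULL) {
  table <- as.data.frame(table)
  if (!is.null(key) && nrow(table)) {
    miss <- setdiff(key, colnames(table))
    if (length(miss))
      stop("key columns absent from table: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(table[, key, drop = FALSE]))
      stop("duplicate rows under key columns ", paste(key, collapse = ", "),
           call. = FALSE)
    table <- table[do.call(order, table[, key, drop = FALSE]), , drop = FALSE]
  }
  fmt <- table
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), NA_character_,
                         sprintf("%.12g", fmt[[j]]))
  write.table(fmt, out_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(out_path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readResultTable <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
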