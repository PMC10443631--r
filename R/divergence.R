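#' @importFrom stats cor hclust dist as.dist
NULL

#' Eigenvalue-weighted variance explained by a binary grouping
#'
#' The divergence score: for each principal component *j* the squared
#' Pearson correlation `R2_j` between the component scores and the binary
#' group indicator (the R-squared of the one-covariate regression) is
#' weighted by the component's explained variance `lambda_j` and normalized
#' by the eigenvalue sum:
#' `V = sum_j R2_j * lambda_j / sum_j lambda_j`.
#' Components with zero eigenvalue contribute to neither sum. `V` lies in
#' `[0, 1]`; 1 requires perfect separation on every positive-eigenvalue
#' component.
#'
#' @param pca a [CohortPCA-class] (or a list with `scores`, `eigenvalues`).
#' @param group a logical/two-level vector, one entry per cell; must contain
#'   both levels.
#' @return the score `V`.
#' @examples
#' sc <- matrix(c(rep(1, 20), rep(-1, 20)), ncol = 1)
#' pca <- list(scores = sc, eigenvalues = 1)
#' varianceExplained(pca, rep(c(TRUE, FALSE), each = 20)) # 1
#' @export
varianceExplained <- function(pca, group) {
  scores <- if (methods::is(pca, "CohortPCA")) pca@scores else pca$scores
  lambda <- if (methods::is(pca, "CohortPCA")) pca@eigenvalues
            else pca$eigenvalues
  if (is.logical(group)) y <- as.numeric(group)
  else {
    lv <- unique(group)
    if (length(lv) != 2 && length(lv) != 1)
      stop("group must be binary", call. = FALSE)
    y <- as.numeric(group == lv[1])
  }
  if (length(unique(y)) < 2)
    stop("group indicator is constant", call. = FALSE)
  if (!any(lambda > 0))
    stop("no component with positive eigenvalue", call. = FALSE)
  keep <- lambda > 0
  S <- scores[, keep, drop = FALSE]
  lam <- lambda[keep]
  S <- sweep(S, 2, colMeans(S))
  yc <- y - mean(y)
  ss_s <- colSums(S^2)
  ss_y <- sum(yc^2)
  num <- as.numeric(crossprod(S, yc))^2
  r2 <- ifelse(ss_s > 0, num / (ss_s * ss_y), 0)
  sum(r2 * lam) / sum(lam)
}

#' Region divergence scan with permutation null
#'
#' For the cells of one cell type, computes a PCA (up to `n_components`
#' components) once, then for every region with at least `min_cells` cells
#' both inside and outside the region computes the observed divergence score
#' `V` (region vs all other regions) and a permutation p-value: the region
#' label vector is shuffled `n_perm` times (one shared shuffle per
#' permutation, evaluated for every eligible region) and
#' `p = k / n_perm` with `k` the number of permuted scores `>=` the observed
#' score. A score is flagged significant only when `k = 0`, the only way to
#' reach `p < 0.0001` at 1000 permutations. Regions failing the minimum-cell
#' rule are omitted with a message. The PCA itself is label-independent, so
#' it is not recomputed per permutation.
#'
#' @param cohort a log-normalized [MarrowCohort-class].
#' @param cell_type restrict to this cell type (default NULL: all cells).
#' @param genes genes for the PCA (default: all).
#' @param n_perm permutations (default 1000).
#' @param min_cells minimum cells per group (default 20).
#' @param n_components PCA components (default 50).
#' @param seed integer seed for the permutation stream.
#' @param pca optional precomputed [CohortPCA-class] over exactly the
#'   selected cells (bypasses the internal PCA).
#' @return data.frame with columns `cell_type`, `region`, `score`, `n_in`,
#'   `n_out`, `n_perm`, `k`, `perm_p`, `significant`.
#' @export
divergenceScan <- function(cohort, cell_type = NULL, genes = NULL,
                           n_perm = 1000L, min_cells = 20L,
                           n_components = 50L, seed = 1L, pca = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  sel <- if (is.null(cell_type)) rep(TRUE, ncol(cohort))
         else cellTypeLabels(cohort) == cell_type
  regions <- regionLabels(cohort)[sel]
  if (length(unique(regions)) < 2)
    stop("need at least 2 regions among the selected cells", call. = FALSE)
  if (is.null(pca))
    pca <- computePCA(cohort, genes = genes, n_components = n_components,
                      cells = sel)
  lam <- pca@eigenvalues
  keep <- lam > 0
  S <- pca@scores[, keep, drop = FALSE]
  lam <- lam[keep]
  S <- sweep(S, 2, colMeans(S))
  ss_s <- colSums(S^2)
  n <- length(regions)
  tab <- table(regions)
  eligible <- names(tab)[tab >= min_cells & (n - tab) >= min_cells]
  skipped <- setdiff(names(tab), eligible)
  if (length(skipped))
    message("regions omitted (fewer than ", min_cells,
            " cells in a group): ", paste(skipped, collapse = ", "))
  if (!length(eligible))
    return(data.frame(cell_type = character(), region = character(),
                      score = numeric(), n_in = integer(), n_out = integer(),
                      n_perm = integer(), k = integer(), perm_p = numeric(),
                      significant = logical()))
  St <- t(S)
  perm_idx <- with_seed(seed,
    vapply(seq_len(n_perm), function(p) sample.int(n), integer(n)))
  rows <- lapply(eligible, function(r) {
    y <- as.numeric(regions == r)
    n_in <- sum(y)
    ss_y <- n_in * (n - n_in) / n
    obs <- sum((as.numeric(St %*% (y - mean(y))))^2 / (ss_s * ss_y) * lam) /
      sum(lam)
    Y <- matrix(y[perm_idx], nrow = n)
    C <- St %*% Y            # centered S => covariance numerators directly
    r2 <- C^2 / (ss_s * ss_y)
    v_perm <- as.numeric(crossprod(lam, r2)) / sum(lam)
    k <- sum(v_perm >= obs)
    data.frame(cell_type = if (is.null(cell_type)) "all" else cell_type,
               region = r, score = obs, n_in = as.integer(n_in),
               n_out = as.integer(n - n_in), n_perm = as.integer(n_perm),
               k = as.integer(k), perm_p = k / n_perm,
               significant = k == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region dendrogram on averaged principal components
#'
#' Averages the component scores per region, computes the Pearson
#' correlation matrix between region profiles, and clusters regions
#' agglomeratively. The default distance is the Euclidean distance between
#' rows of the correlation matrix with complete linkage (the behavior of the
#' standard single-cell dendrogram implementation); `method =
#' "one_minus_cor_average"` instead uses `1 - r` with average linkage.
#' Regions are ordered lexicographically before clustering so ties break
#' deterministically.
#'
#' @param pca a [CohortPCA-class] over all cells of interest.
#' @param regions character vector of region labels, one per PCA row.
#' @param method distance/linkage variant (see above).
#' @return a list with `regions`, `cor_matrix`, `hclust`, and a `newick`
#'   string whose branch lengths derive from the merge heights.
#' @export
regionDendrogram <- function(pca, regions,
                             method = c("score_cor_complete",
                                        "one_minus_cor_average")) {
  method <- match.arg(method)
  stopifnot(length(regions) == nrow(pca@scores))
  lv <- sort(unique(as.character(regions)))
  if (length(lv) < 2) stop("need at least 2 regions", call. = FALSE)
  prof <- t(vapply(lv, function(r)
    colMeans(pca@scores[regions == r, , drop = FALSE]),
    numeric(ncol(pca@scores))))
  C <- cor(t(prof))
  dimnames(C) <- list(lv, lv)
  if (method == "score_cor_complete") {
    hc <- hclust(dist(C), method = "complete")
  } else {
    hc <- hclust(as.dist(1 - C), method = "average")
  }
  phy <- ape::as.phylo(hc)
  list(regions = lv, cor_matrix = C, hclust = hc,
       newick = ape::write.tree(phy))
}
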