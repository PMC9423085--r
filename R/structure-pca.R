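# Population-structure PCA: genotype PCA and normalized-depth PCA over
# CNV regions.

pca_core <- function(X, n_components) {
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  total <- sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  # deterministic sign: the largest-magnitude loading on each component
  # is positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 variance_fraction = if (total > 0)
                   sv$d[seq_len(n_components)]^2 / total
                 else rep(0, n_components),
                 loadings = loadings),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (var %%: %s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f", 100 * x$variance_fraction), collapse = ", ")))
  invisible(x)
}

#' Genotype PCA
#'
#' Standard population-structure PCA: per-SNP centering and unit-variance
#' scaling (monomorphic SNPs dropped), missing genotypes mean-imputed,
#' eigendecomposition of the sample covariance. Component signs are fixed
#' (largest-magnitude loading positive) so results are reproducible.
#'
#' @param gm a [genotype_matrix()] (>= 2 samples, >= 2 polymorphic sites).
#' @param n_components number of components to return (default 10).
#' @return A `pca_result`: `scores` (samples x components, rows named by
#'   sample id), `variance_fraction`, `loadings`.
#' @export
genotype_pca <- function(gm, n_components = 10L) {
  G <- gm$geno
  keep <- apply(G, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (sum(keep) < 2L) stopf("need >= 2 polymorphic sites")
  G <- G[, keep, drop = FALSE]
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  out <- pca_core(scale(G), n_components)
  rownames(out$scores) <- gm$sample_ids
  out
}

#' PCA of normalized read depth over CNV regions
#'
#' Mirrors the depth-based view of population structure: each sample is
#' summarized by its mean normalized depth over every CNV region, and the
#' same PCA contract as [genotype_pca()] is applied to that matrix.
#'
#' @param ndm a `norm_depth_matrix` from [normalize_depth()].
#' @param regions data.frame of CNV regions (`region_id`, `chrom`,
#'   `start`, `end`); must be non-empty.
#' @param n_components number of components (default 10).
#' @return A `pca_result` with rows named by sample id.
#' @export
depth_pca <- function(ndm, regions, n_components = 10L) {
  if (nrow(regions) == 0L) stopf("no CNV regions supplied")
  X <- region_mean_z(ndm, regions)
  X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  if (ncol(X) == 0L) stopf("no CNV regions overlap the depth targets")
  out <- pca_core(X, min(n_components, ncol(X)))
  rownames(out$scores) <- ndm$samples
  out
}
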