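#' Genotype matrix for biallelic SNP data
#'
#' The substrate for all SNP statistics: an (samples x sites) integer matrix
#' of alt-allele dosages in \{0, 1, 2, NA\} plus per-site metadata.
#'
#' @param geno integer matrix, rows = samples, columns = sites, entries in
#'   \{0, 1, 2\} (alt-allele count) or `NA` for missing calls.
#' @param sites data.frame with one row per site and columns `chrom`,
#'   `pos` (1-based bp), `ref`, `alt` (comma-separated if multiallelic),
#'   `qual` (site quality), `mean_depth` (mean depth across samples).
#'   A logical `biallelic` column is added if absent.
#' @param sample_ids character vector of sample names, one per row of `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `sites`, `sample_ids`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sample_ids))
    stopf("geno has %d rows but %d sample ids", nrow(geno), length(sample_ids))
  if (ncol(geno) != nrow(sites))
    stopf("geno has %d columns but %d site records", ncol(geno), nrow(sites))
  need <- c("chrom", "pos", "ref", "alt", "qual", "mean_depth")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stopf("sites is missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(sites$biallelic))
    sites$biallelic <- !grepl(",", sites$alt, fixed = TRUE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  bad <- unlist(tapply(sites$pos, sites$chrom, function(p) any(diff(p) <= 0)))
  if (any(bad))
    stopf("site positions must be strictly increasing within each chromosome")
  dimnames(geno) <- list(sample_ids, NULL)
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d chromosomes), %.2f%% missing\n",
              n_samples(x), n_sites(x), length(unique(x$sites$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname genotype_matrix
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site and/or sample
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical/integer index over sites (optional).
#' @param samples logical/integer index or character ids over samples (optional).
#' @return A `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  geno <- gm$geno
  sdf <- gm$sites
  ids <- gm$sample_ids
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    sdf <- sdf[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    geno <- geno[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  genotype_matrix(geno, sdf, ids)
}

#' Per-site missingness fraction
#' @param gm a [genotype_matrix()].
#' @return Numeric vector, one value per site.
#' @export
site_missingness <- function(gm) colMeans(is.na(gm$geno))

# Alt and total non-missing allele-copy counts per site.
allele_counts <- function(gm) {
  alt <- colSums(gm$geno, na.rm = TRUE)
  n <- 2L * colSums(!is.na(gm$geno))
  list(alt = alt, total = n, minor = pmin(alt, n - alt))
}
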