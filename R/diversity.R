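# Per-cluster diversity: segregating sites, rarefied allelic and private
# allelic richness, observed SFS (SNPs and CNV carriers), and the
# Watterson-expected SFS.

#' Segregating sites per cluster
#'
#' A site segregates in a cluster iff at least two alleles are observed
#' among the non-missing genotypes of that cluster's samples.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample`, `cluster`.
#' @return Named integer vector, one count per cluster.
#' @export
segregating_sites <- function(gm, popmap) {
  clusters <- sort(unique(popmap$cluster))
  vapply(clusters, function(cl) {
    g <- gm$geno[gm$sample_ids %in% popmap$sample[popmap$cluster == cl], ,
                 drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    tot <- 2L * colSums(!is.na(g))
    sum(alt > 0L & alt < tot)
  }, integer(1))
}

# P(allele with N_a copies among N present in a subsample of g copies)
rarefy_presence <- function(N_a, N, g) {
  ifelse(N_a == 0, 0, 1 - exp(lchoose(N - N_a, g) - lchoose(N, g)))
}

#' Rarefied allelic and private allelic richness
#'
#' Standardizes diversity to a common number of sampled gene copies `g` so
#' clusters of unequal size are comparable. Per locus and allele with
#' `N_a` copies among `N` in a cluster, the probability the allele appears
#' in a subsample of `g` copies is `1 - C(N - N_a, g) / C(N, g)`; allelic
#' richness sums this over alleles and averages over loci. Private
#' richness additionally multiplies, for each other cluster, the
#' probability that a size-`g` subsample of that cluster contains no copy
#' of the allele. Loci where any cluster has fewer than `g` usable gene
#' copies are skipped (and counted in `n_loci_skipped`).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample`, `cluster`.
#' @param g integer vector of standardized subsample sizes (gene copies,
#'   each >= 1).
#' @return data.frame with columns `cluster`, `g`, `allelic_richness`,
#'   `private_richness`, `n_loci_used`, `n_loci_skipped`.
#' @export
rarefied_richness <- function(gm, popmap, g) {
  if (any(g < 1)) stopf("g must be >= 1")
  clusters <- sort(unique(popmap$cluster))
  K <- length(clusters)
  idx <- lapply(clusters, function(cl)
    gm$sample_ids %in% popmap$sample[popmap$cluster == cl])
  # per-cluster alt-allele and total gene-copy counts, loci x clusters
  altc <- do.call(cbind, lapply(idx, function(i)
    colSums(gm$geno[i, , drop = FALSE], na.rm = TRUE)))
  totc <- do.call(cbind, lapply(idx, function(i)
    2L * colSums(!is.na(gm$geno[i, , drop = FALSE]))))
  out <- list()
  for (gg in sort(unique(as.integer(g)))) {
    usable <- rowSums(totc >= gg) == K
    for (k in seq_len(K)) {
      N <- totc[usable, k]; Na <- altc[usable, k]
      pres_alt <- rarefy_presence(Na, N, gg)
      pres_ref <- rarefy_presence(N - Na, N, gg)
      rich <- mean(pres_alt + pres_ref)
      abs_other_alt <- rep(1, sum(usable)); abs_other_ref <- rep(1, sum(usable))
      for (j in setdiff(seq_len(K), k)) {
        Nj <- totc[usable, j]; Naj <- altc[usable, j]
        abs_other_alt <- abs_other_alt * (1 - rarefy_presence(Naj, Nj, gg))
        abs_other_ref <- abs_other_ref * (1 - rarefy_presence(Nj - Naj, Nj, gg))
      }
      priv <- mean(pres_alt * abs_other_alt + pres_ref * abs_other_ref)
      out[[length(out) + 1L]] <- data.frame(
        cluster = clusters[k], g = gg, allelic_richness = rich,
        private_richness = priv, n_loci_used = sum(usable),
        n_loci_skipped = sum(!usable), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Observed SNP site frequency spectrum for a cluster
#'
#' Counts sites by derived (alt) allele frequency class among the
#' cluster's gene copies. With missing data, each site is projected onto a
#' common size `n_project` by the hypergeometric down-projection, which
#' preserves segregating sites while standardizing n; classes 0 and n
#' (monomorphic after projection) carry no mass in the spectrum.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample`, `cluster`.
#' @param cluster cluster label.
#' @param n_project chromosomes to project onto; default = the minimum
#'   non-missing gene-copy count over sites (capped at 2 x cluster size).
#' @param folded fold the spectrum to minor-allele classes?
#' @return A list of class `sfs_spectrum`: `n` (chromosomes), `counts`
#'   (classes 1..n-1), `kind`.
#' @export
observed_sfs_snp <- function(gm, popmap, cluster, n_project = NULL,
                             folded = FALSE) {
  samp <- popmap$sample[popmap$cluster == cluster]
  if (!length(samp)) stopf("cluster '%s' is empty", cluster)
  g <- gm$geno[gm$sample_ids %in% samp, , drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(g))
  seg <- alt > 0L & alt < tot
  alt <- alt[seg]; tot <- tot[seg]
  if (is.null(n_project))
    n_project <- if (length(tot)) min(tot) else 2L * length(samp)
  n <- as.integer(n_project)
  counts <- numeric(max(n - 1L, 1L))
  for (i in seq_along(alt)) {
    if (tot[i] < n) next                    # cannot project up; skip site
    if (tot[i] == n) {
      counts[alt[i]] <- counts[alt[i]] + 1
    } else {
      j <- 1:(n - 1L)
      counts[j] <- counts[j] + dhyper(j, alt[i], tot[i] - alt[i], n)
    }
  }
  if (folded) {
    half <- floor(n / 2)
    fc <- numeric(half)
    for (j in seq_len(half))
      fc[j] <- counts[j] + if (j != n - j) counts[n - j] else 0
    counts <- fc
  }
  structure(list(n = n, counts = counts,
                 kind = if (folded) "observed_snp_folded" else "observed_snp"),
            class = "sfs_spectrum")
}

#' Observed CNV carrier-frequency spectrum for a cluster
#'
#' Depth-based CNV calls do not resolve allele dosage, so the CNV spectrum
#' counts carrier *samples* per region; n is the cluster sample count and
#' regions carried by every sample (class n) are excluded.
#'
#' @param catalog a [cnv_regions()] catalog.
#' @param popmap data.frame `sample`, `cluster`.
#' @param cluster cluster label.
#' @return An `sfs_spectrum` (`kind = "observed_cnv"`).
#' @export
observed_sfs_cnv <- function(catalog, popmap, cluster) {
  samp <- popmap$sample[popmap$cluster == cluster]
  if (!length(samp)) stopf("cluster '%s' is empty", cluster)
  n <- length(samp)
  carr <- unique(catalog$carriers[catalog$carriers$sample %in% samp,
                                  c("region_id", "sample")])
  k <- table(carr$region_id)
  counts <- numeric(max(n - 1L, 1L))
  for (j in seq_len(n - 1L)) counts[j] <- sum(k == j)
  structure(list(n = n, counts = counts, kind = "observed_cnv"),
            class = "sfs_spectrum")
}

#' Watterson-expected site frequency spectrum
#'
#' Under the standard neutral model the expected count in derived-allele
#' class i is theta_W / i, with theta_W = S / sum_(i=1..n-1) 1/i estimated
#' from the observed number of segregating sites S; the expected counts
#' total S exactly.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @param S number of segregating sites (>= 0).
#' @return An `sfs_spectrum` (`kind = "expected_watterson"`) with an extra
#'   element `theta_w`.
#' @export
expected_sfs_watterson <- function(n, S) {
  if (n < 2) stopf("n must be >= 2")
  if (S < 0) stopf("S must be >= 0")
  i <- 1:(n - 1)
  a1 <- sum(1 / i)
  theta <- S / a1
  structure(list(n = as.integer(n), counts = theta / i,
                 kind = "expected_watterson", theta_w = theta),
            class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("sfs_spectrum (%s): n = %d, %d classes, total = %.2f\n",
              x$kind, x$n, length(x$counts), sum(x$counts)))
  invisible(x)
}
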