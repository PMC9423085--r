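# Population differentiation: per-site and windowed Weir-Cockerham F_ST
# from SNPs, and V_ST from normalized read depth for CNV regions.

#' Per-site Weir-Cockerham F_ST variance components
#'
#' Implements the diploid variance-components estimator for two
#' populations with unequal sample sizes: per site, `a` (among
#' populations), `b` (among individuals within populations) and `c`
#' (within individuals), with theta_hat = a / (a + b + c). Sites where
#' a + b + c = 0 (no variance) are flagged missing. Only individuals with
#' non-missing genotypes at a site enter that site's components; sites
#' with fewer than 2 genotyped individuals in either group are missing.
#'
#' @param gm a [genotype_matrix()].
#' @param samples_a,samples_b disjoint character vectors of sample ids.
#' @return data.frame with one row per site: `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta` (NA when undefined).
#' @export
weir_cockerham_fst <- function(gm, samples_a, samples_b) {
  if (length(intersect(samples_a, samples_b)))
    stopf("sample groups overlap")
  ga <- gm$geno[match(samples_a, gm$sample_ids), , drop = FALSE]
  gb <- gm$geno[match(samples_b, gm$sample_ids), , drop = FALSE]
  comp_pop <- function(g) {
    n <- colSums(!is.na(g))                       # genotyped individuals
    p <- colSums(g, na.rm = TRUE) / (2 * n)       # alt freq
    h <- colSums(g == 1L, na.rm = TRUE) / n       # observed het proportion
    list(n = n, p = p, h = h)
  }
  A <- comp_pop(ga); B <- comp_pop(gb)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- A$n < 2 | B$n < 2
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             a = a, b = b, c = cc, theta = theta, stringsAsFactors = FALSE)
}

#' Windowed mean F_ST (ratio of sums)
#'
#' Sliding windows tile each chromosome from 0 to its end; the window
#' value is the multi-locus Weir-Cockerham combination
#' sum(a) / sum(a + b + c) over usable sites in the window. Windows with
#' no usable site are flagged missing.
#'
#' @param per_site output of [weir_cockerham_fst()].
#' @param chrom_lengths named vector of chromosome lengths (bp); inferred
#'   from the largest site position when `NULL`.
#' @param window,step window and step sizes in bp (defaults 100 kb / 50 kb).
#' @param mean_of_ratios use the mean of per-site theta instead of the
#'   ratio-of-sums combination (for strict replication of per-site-mean
#'   windowing tools).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `n_variants`, `value`.
#' @export
windowed_fst <- function(per_site, chrom_lengths = NULL, window = 100000,
                         step = 50000, mean_of_ratios = FALSE) {
  if (step > window) warnf("step > window leaves gaps between windows")
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(per_site$chrom, per_site$pos)
  win <- tile_windows(chrom_lengths, window, step)
  usable <- !is.na(per_site$a + per_site$b + per_site$c)
  win$n_variants <- NA_integer_
  win$value <- NA_real_
  for (i in seq_len(nrow(win))) {
    inw <- usable & per_site$chrom == win$chrom[i] &
      per_site$pos > win$start[i] & per_site$pos <= win$end[i]
    win$n_variants[i] <- sum(inw)
    if (win$n_variants[i] > 0L) {
      if (mean_of_ratios) {
        win$value[i] <- mean(per_site$theta[inw], na.rm = TRUE)
      } else {
        denom <- sum(per_site$a[inw] + per_site$b[inw] + per_site$c[inw])
        win$value[i] <- if (denom != 0) sum(per_site$a[inw]) / denom else NA_real_
      }
    }
  }
  win
}

#' V_ST differentiation from normalized read depth
#'
#' For each CNV region, each sample's value is its mean normalized depth
#' over the region's spanned targets. V_T is the sample variance (n-1
#' denominator) over the pooled two-cluster values; V_S is the
#' sample-size-weighted mean of the within-cluster variances,
#' (n_a Var_a + n_b Var_b) / (n_a + n_b); V_ST = (V_T - V_S) / V_T,
#' missing when V_T = 0.
#'
#' @param ndm a `norm_depth_matrix` from [normalize_depth()].
#' @param regions data.frame of CNV regions (`region_id`, `chrom`,
#'   `start`, `end`; 0-based half-open).
#' @param popmap data.frame `sample`, `cluster`.
#' @param cluster_a,cluster_b cluster labels (each with >= 2 samples).
#' @return data.frame per region: `region_id`, `v_t`, `v_s`, `v_st`.
#' @export
vst <- function(ndm, regions, popmap, cluster_a, cluster_b) {
  sa <- popmap$sample[popmap$cluster == cluster_a]
  sb <- popmap$sample[popmap$cluster == cluster_b]
  if (length(sa) < 2L || length(sb) < 2L)
    stopf("both clusters need >= 2 samples")
  vals <- region_mean_z(ndm, regions)
  ia <- match(sa, ndm$samples); ib <- match(sb, ndm$samples)
  out <- data.frame(region_id = regions$region_id, v_t = NA_real_,
                    v_s = NA_real_, v_st = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    xa <- vals[ia, i]; xb <- vals[ib, i]
    vt <- var(c(xa, xb))
    vs <- (length(xa) * var(xa) + length(xb) * var(xb)) / (length(xa) + length(xb))
    out$v_t[i] <- vt
    out$v_s[i] <- vs
    out$v_st[i] <- if (is.na(vt) || vt == 0) NA_real_ else (vt - vs) / vt
  }
  out
}

# samples x regions matrix of mean z over each region's spanned targets
region_mean_z <- function(ndm, regions) {
  hits <- overlap_pairs0(regions, ndm$targets)
  vals <- matrix(NA_real_, nrow = length(ndm$samples), ncol = nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tg <- hits$s_idx[hits$q_idx == i]
    if (length(tg))
      vals[, i] <- rowMeans(ndm$z[, tg, drop = FALSE])
  }
  vals
}

#' Mean pairwise V_ST matrix over all cluster pairs
#'
#' @inheritParams vst
#' @return list with `matrix` (clusters x clusters, mean per-region V_ST)
#'   and `per_region` (data.frame of every pair's per-region results).
#' @export
vst_matrix <- function(ndm, regions, popmap) {
  clusters <- sort(unique(popmap$cluster))
  M <- matrix(NA_real_, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  per <- list()
  for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
    if (j <= i) next
    r <- vst(ndm, regions, popmap, clusters[i], clusters[j])
    M[i, j] <- M[j, i] <- mean(r$v_st, na.rm = TRUE)
    r$cluster_a <- clusters[i]; r$cluster_b <- clusters[j]
    per[[length(per) + 1L]] <- r
  }
  list(matrix = M, per_region = do.call(rbind, per))
}

#' Mean pairwise multi-locus F_ST matrix over all cluster pairs
#'
#' Multi-locus theta per pair is the genome-wide ratio of sums
#' sum(a) / sum(a + b + c).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample`, `cluster`.
#' @return clusters x clusters numeric matrix.
#' @export
fst_matrix <- function(gm, popmap) {
  clusters <- sort(unique(popmap$cluster))
  M <- matrix(NA_real_, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
    if (j <= i) next
    ps <- weir_cockerham_fst(gm,
                             popmap$sample[popmap$cluster == clusters[i]],
                             popmap$sample[popmap$cluster == clusters[j]])
    ok <- !is.na(ps$a + ps$b + ps$c)
    M[i, j] <- M[j, i] <- sum(ps$a[ok]) / sum(ps$a[ok] + ps$b[ok] + ps$c[ok])
  }
  M
}
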