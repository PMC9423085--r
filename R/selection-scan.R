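# Selection scans: windowed Tajima's D, H12 haplotype homozygosity with
# peak finding, PCA-based outlier SNPs, and the multi-method gene-level
# consensus.

tajima_constants <- function(n) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D for one cluster
#'
#' Nonoverlapping windows tile each chromosome; per window, pi is the sum
#' over segregating sites of 2 k (m - k) / (m (m - 1)) with k the alt
#' count among m non-missing chromosomes, theta_W = S / a1(n), and
#' D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1)) with the standard
#' constants at n = the (rounded) mean non-missing chromosome count over
#' the window's segregating sites. Windows with S < `min_sites` are
#' flagged missing.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample`, `cluster`.
#' @param cluster cluster label (>= 4 samples).
#' @param window window size in bp (default 100 kb, nonoverlapping).
#' @param chrom_lengths named vector of chromosome lengths; inferred when
#'   `NULL`.
#' @param min_sites minimum segregating sites per window (default 3).
#' @return data.frame `chrom`, `start`, `end`, `n_variants`, `value`.
#' @export
tajimas_d_windows <- function(gm, popmap, cluster, window = 100000,
                              chrom_lengths = NULL, min_sites = 3L) {
  samp <- popmap$sample[popmap$cluster == cluster]
  if (length(samp) < 4L) stopf("cluster '%s' has < 4 samples", cluster)
  g <- gm$geno[gm$sample_ids %in% samp, , drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  m <- 2L * colSums(!is.na(g))
  seg <- alt > 0L & alt < m & m >= 4L
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(gm$sites$chrom, gm$sites$pos)
  win <- tile_windows(chrom_lengths, window, window)
  win$n_variants <- NA_integer_
  win$value <- NA_real_
  for (i in seq_len(nrow(win))) {
    inw <- seg & gm$sites$chrom == win$chrom[i] &
      gm$sites$pos > win$start[i] & gm$sites$pos <= win$end[i]
    S <- sum(inw)
    win$n_variants[i] <- S
    if (S < min_sites) next
    k <- alt[inw]; mm <- m[inw]
    ppi <- sum(2 * k * (mm - k) / (mm * (mm - 1)))
    n <- round(mean(mm))
    cst <- tajima_constants(n)
    vr <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (vr <= 0) next
    win$value[i] <- (ppi - S / cst$a1) / sqrt(vr)
  }
  win
}

# Pseudo-haplotypes for a selfing panel: homozygous calls map to one
# allele, heterozygous calls to NA. Returns samples x sites matrix in
# {0, 1, NA}.
pseudo_haplotypes <- function(geno) {
  h <- matrix(NA_integer_, nrow(geno), ncol(geno))
  h[geno == 0L] <- 0L
  h[geno == 2L] <- 1L
  h
}

#' H12 haplotype-homozygosity scan
#'
#' Slides SNP-count windows along each chromosome (default 50 SNPs,
#' advancing 5 SNPs). Samples are reduced to pseudo-haplotypes
#' (heterozygous calls treated as missing, appropriate for a highly
#' selfing panel); haplotypes with more than `max_missing` missing sites
#' in a window are dropped, and remaining missing entries are filled with
#' the window's major allele. H12 = (p1 + p2)^2 + sum_(i>=3) p_i^2 over
#' the sorted haplotype frequencies. Chromosomes with fewer SNPs than one
#' window are skipped with a warning.
#'
#' @param gm a [genotype_matrix()] (optionally restricted to one cluster's
#'   samples first; the default is the full panel).
#' @param window_snps SNPs per window (default 50).
#' @param step_snps SNPs between window starts (default 5).
#' @param max_missing maximum fraction of missing pseudo-haplotype sites
#'   per window before a sample is dropped (default 0.2).
#' @return data.frame per window: `chrom`, `start`, `end` (bp of first and
#'   last SNP), `center_bp`, `n_haplotypes`, `h12`.
#' @export
h12_scan <- function(gm, window_snps = 50L, step_snps = 5L, max_missing = 0.2) {
  hap <- pseudo_haplotypes(gm$geno)
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < window_snps) {
      warnf("chromosome %s has %d SNPs (< %d); skipped", ch, length(idx), window_snps)
      next
    }
    starts <- seq(1L, length(idx) - window_snps + 1L, by = step_snps)
    for (s0 in starts) {
      cols <- idx[s0:(s0 + window_snps - 1L)]
      h12 <- h12_window(hap[, cols, drop = FALSE], max_missing)
      pos <- gm$sites$pos[cols]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = pos[1L], end = pos[length(pos)],
        center_bp = pos[ceiling(window_snps / 2)],
        n_haplotypes = h12$n, h12 = h12$h12, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      center_bp = integer(0), n_haplotypes = integer(0),
                      h12 = numeric(0)))
  do.call(rbind, out)
}

h12_window <- function(hapwin, max_missing = 0.2) {
  miss <- rowMeans(is.na(hapwin))
  hapwin <- hapwin[miss <= max_missing, , drop = FALSE]
  if (nrow(hapwin) == 0L) return(list(h12 = NA_real_, n = 0L))
  # fill residual missing with the window's per-site major allele
  for (j in seq_len(ncol(hapwin))) {
    na <- is.na(hapwin[, j])
    if (any(na)) {
      maj <- if (sum(hapwin[, j] == 1L, na.rm = TRUE) * 2L >
                 sum(!is.na(hapwin[, j]))) 1L else 0L
      hapwin[na, j] <- maj
    }
  }
  key <- apply(hapwin, 1L, paste, collapse = "")
  p <- sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
  h12 <- if (length(p) == 1L) p[1L]^2 else
    (p[1L] + p[2L])^2 + sum(p[-(1:2)]^2)
  list(h12 = h12, n = nrow(hapwin))
}

#' Peaks in an H12 track
#'
#' Candidate peaks are contiguous runs of windows with H12 above a
#' threshold (default: track median + 2 x MAD). Peaks spanning no more
#' than `min_length_bp` are discarded (sweeps shorter than the LD decay
#' scale are likely false positives); the remaining peaks are ranked by
#' their maximum H12 (ties broken by leftmost start) and the top
#' `top_k` kept per chromosome.
#'
#' @param h12_track output of [h12_scan()], sorted by position.
#' @param top_k maximum peaks kept per chromosome (default 5).
#' @param min_length_bp minimum peak span in bp (default 150 kb, a typical
#'   LD-decay distance for a selfing crop).
#' @param threshold H12 cutoff; `NULL` = median + 2 x MAD of the track.
#' @return data.frame per peak: `chrom`, `start`, `end`, `max_h12`, `rank`.
#' @export
find_peaks <- function(h12_track, top_k = 5L, min_length_bp = 150000,
                       threshold = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      max_h12 = numeric(0), rank = integer(0))
  if (nrow(h12_track) == 0L) return(empty)
  vals <- h12_track$h12
  if (is.null(threshold))
    threshold <- median(vals, na.rm = TRUE) + 2 * mad(vals, na.rm = TRUE)
  out <- list()
  for (ch in unique(h12_track$chrom)) {
    tr <- h12_track[h12_track$chrom == ch, , drop = FALSE]
    above <- !is.na(tr$h12) & tr$h12 > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    peaks <- lapply(which(r$values), function(j) {
      rows <- starts[j]:ends[j]
      data.frame(chrom = ch, start = min(tr$start[rows]), end = max(tr$end[rows]),
                 max_h12 = max(tr$h12[rows]), stringsAsFactors = FALSE)
    })
    peaks <- do.call(rbind, peaks)
    # overlapping window spans can make adjacent candidate runs overlap
    # in bp; such runs are one peak and are merged before filtering
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    merged <- peaks[1, , drop = FALSE]
    if (nrow(peaks) > 1) for (i in 2:nrow(peaks)) {
      last <- nrow(merged)
      if (peaks$start[i] < merged$end[last]) {
        merged$end[last] <- max(merged$end[last], peaks$end[i])
        merged$max_h12[last] <- max(merged$max_h12[last], peaks$max_h12[i])
      } else merged <- rbind(merged, peaks[i, ])
    }
    peaks <- merged[merged$end - merged$start > min_length_bp, , drop = FALSE]
    if (nrow(peaks) == 0L) next
    ord <- order(-peaks$max_h12, peaks$start)
    peaks <- peaks[head(ord, top_k), , drop = FALSE]
    peaks$rank <- seq_len(nrow(peaks))
    out[[length(out) + 1L]] <- peaks
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PCA-based outlier SNP scan
#'
#' Flags SNPs whose association with the top principal components of the
#' genotype matrix is an outlier relative to the genome-wide background
#' (the population-structure-aware outlier approach). Genotypes are
#' standardized per SNP (monomorphic SNPs dropped, missing values
#' mean-imputed); per SNP the vector of regression z-statistics against
#' the top `n_pcs` sample scores is summarized as a Mahalanobis distance
#' under a robust covariance estimate (so the outliers being hunted do
#' not mask themselves), rescaled by the genomic inflation factor (median
#' distance / chi-squared_(n_pcs) median), and converted to a chi-squared
#' p-value on `n_pcs` degrees of freedom. Benjamini-Hochberg adjusted
#' p-values below `alpha` are flagged. Apply the second-pass variant
#' filter (higher MAC, thinning, CNV exclusion) beforehand: the
#' chi-squared calibration assumes well-informed per-SNP statistics and
#' rare variants inflate the tail.
#'
#' @param gm a [genotype_matrix()].
#' @param n_pcs number of principal components capturing the structure
#'   (>= 1 and < sample count).
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.01).
#' @return A list of class `outlier_set`: `method` ("pca_outlier"),
#'   `snps` (data.frame `chrom`, `pos`, `stat`, `p_value`, `p_adj`,
#'   `flagged`), `gif` (genomic inflation factor), `n_pcs`, `alpha`.
#' @export
pca_outlier_scan <- function(gm, n_pcs, alpha = 0.01) {
  if (n_pcs < 1L || n_pcs >= n_samples(gm))
    stopf("n_pcs must be >= 1 and < sample count")
  G <- gm$geno
  keep <- apply(G, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
  G <- G[, keep, drop = FALSE]
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  Gs <- scale(G)
  n <- nrow(Gs)
  sv <- svd(Gs, nu = n_pcs, nv = 0)
  U <- sv$u[, seq_len(n_pcs), drop = FALSE]      # orthonormal score directions
  B <- crossprod(U, Gs)                          # n_pcs x SNPs
  rss <- pmax(colSums(Gs^2) - colSums(B^2), 0)
  # floor the residual SD: a SNP (near-)perfectly collinear with a PC --
  # e.g. every SNP on a swept haplotype -- has rss ~ 0 and must come out
  # as an extreme statistic, not a degenerate one
  sigma <- pmax(sqrt(rss / pmax(n - n_pcs - 1L, 1L)), 1e-8)
  Z <- t(B) / sigma                              # SNPs x n_pcs
  cr <- MASS::cov.rob(Z)
  D <- mahalanobis(Z, cr$center, cr$cov)
  gif <- median(D) / qchisq(0.5, df = n_pcs)
  p <- pchisq(D / gif, df = n_pcs, lower.tail = FALSE)
  p_adj <- p.adjust(p, method = "BH")
  snps <- data.frame(chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
                     stat = D / gif, p_value = p, p_adj = p_adj,
                     flagged = p_adj < alpha, stringsAsFactors = FALSE)
  structure(list(method = "pca_outlier", snps = snps, gif = gif,
                 n_pcs = n_pcs, alpha = alpha),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set (%s): %d/%d SNPs flagged at alpha = %g (GIF %.2f)\n",
              x$method, sum(x$snps$flagged), nrow(x$snps), x$alpha, x$gif))
  invisible(x)
}

#' Multi-method consensus of candidate genes under selection
#'
#' Genes detected by at least `min_methods` of the supplied per-method
#' gene sets are retained as consensus candidates; an externally produced
#' outlier gene list (e.g. from an allele-frequency F-model tool) may be
#' one of the sets.
#'
#' @param method_gene_sets named list of character vectors of gene ids.
#' @param min_methods minimum number of methods (default 2).
#' @return Character vector of consensus gene ids, with a per-method /
#'   per-overlap count report in `attr(, "report")`.
#' @export
consensus_candidates <- function(method_gene_sets, min_methods = 2L) {
  if (min_methods > length(method_gene_sets))
    stopf("min_methods (%d) exceeds number of method sets (%d)",
          min_methods, length(method_gene_sets))
  sets <- lapply(method_gene_sets, unique)
  all_genes <- unique(unlist(sets))
  hits <- vapply(all_genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  consensus <- all_genes[hits >= min_methods]
  report <- list(
    per_method = vapply(sets, length, integer(1)),
    n_by_support = table(hits),
    n_consensus = length(consensus))
  structure(sort(consensus), report = report)
}

#' Map intervals or SNP hits to overlapping genes
#'
#' Sweep-scan peaks map to every gene whose interval overlaps the peak
#' (half-open overlap, optionally extended by `flank_bp`); outlier SNPs
#' map to the gene containing them.
#'
#' @param hits either a data.frame of intervals (`chrom`, `start`, `end`;
#'   0-based half-open) or of SNPs (`chrom`, `pos`).
#' @param annotation data.frame of gene intervals (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param flank_bp extension added to each side of every hit (default 0).
#' @return Sorted character vector of gene ids.
#' @export
regions_to_genes <- function(hits, annotation, flank_bp = 0) {
  if (nrow(hits) == 0L) return(character(0))
  iv <- if ("pos" %in% names(hits) && !("end" %in% names(hits)))
    data.frame(chrom = hits$chrom, start = hits$pos - 1L, end = hits$pos)
  else hits[, c("chrom", "start", "end")]
  iv$start <- pmax(0L, iv$start - flank_bp)
  iv$end <- iv$end + flank_bp
  ov <- overlap_pairs0(iv, annotation)
  sort(unique(annotation$gene_id[ov$s_idx]))
}
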