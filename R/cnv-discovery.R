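# CNV discovery from exome read depth: target filtering, PCA
# normalization, and a three-state (DEL / diploid / DUP) HMM, followed by
# region merging, frequencies, burden, and chromosome-level correlations.

#' Per-target read-depth matrix
#'
#' @param targets data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), sorted and non-overlapping per chromosome.
#' @param samples character vector of sample ids.
#' @param depth numeric matrix, rows = samples, columns = targets,
#'   non-negative mean coverage.
#' @return An object of class `depth_matrix`.
#' @export
depth_matrix <- function(targets, samples, depth) {
  depth <- as.matrix(depth)
  if (nrow(depth) != length(samples) || ncol(depth) != nrow(targets))
    stopf("depth must be %d samples x %d targets", length(samples), nrow(targets))
  if (any(depth < 0, na.rm = TRUE)) stopf("depth must be non-negative")
  if (any(targets$end <= targets$start)) stopf("targets must have end > start")
  for (ch in unique(targets$chrom)) {
    t_ch <- targets[targets$chrom == ch, ]
    if (is.unsorted(t_ch$start) || any(t_ch$start[-1] < t_ch$end[-nrow(t_ch)]))
      stopf("targets must be sorted and non-overlapping within chromosome %s", ch)
  }
  rownames(depth) <- samples
  rownames(targets) <- NULL
  structure(list(targets = targets, samples = samples, depth = depth),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth_matrix: %d samples x %d targets, mean depth %.1fx\n",
              length(x$samples), nrow(x$targets), mean(x$depth)))
  invisible(x)
}

#' Filter exome targets before CNV calling
#'
#' Drops targets shorter than `min_size_bp` or whose cross-sample mean
#' depth falls outside `[min_mean_depth, max_mean_depth]`. Target order is
#' preserved.
#'
#' @param dm a [depth_matrix()].
#' @param min_size_bp minimum target span (default 100 bp).
#' @param min_mean_depth minimum cross-sample mean depth (default 3x).
#' @param max_mean_depth maximum cross-sample mean depth (default 3000x).
#' @return A filtered `depth_matrix`; errors if nothing survives.
#' @export
filter_targets <- function(dm, min_size_bp = 100, min_mean_depth = 3,
                           max_mean_depth = 3000) {
  span <- dm$targets$end - dm$targets$start
  md <- colMeans(dm$depth)
  keep <- span >= min_size_bp & md >= min_mean_depth & md <= max_mean_depth
  if (!any(keep)) stopf("all targets removed by target filtering")
  depth_matrix(dm$targets[keep, , drop = FALSE], dm$samples,
               dm$depth[, keep, drop = FALSE])
}

#' PCA-normalize read depth into z-scores
#'
#' Removes systematic depth structure the way exome CNV callers do:
#' per-target (column) centering, principal components computed across
#' samples, subtraction of the projections onto the top components, then a
#' per-sample z-score of the residuals (every sample row gets mean 0 over
#' targets). Two estimation steps are robustified for panels with few
#' targets, where rare-CNV outliers are not a negligible share of the
#' total variance: columns are centered by a 20%-trimmed mean (so
#' carriers of a rare CNV do not drag the reference level of its targets,
#' while the centering stays smooth enough to keep low-rank batch
#' structure low-rank), and both the principal components and the
#' subtracted structure are estimated from a copy of the matrix
#' winsorized at 2 column-MADs (so CNV outliers can neither leak into the
#' removed components nor contaminate the projection coefficients and
#' imprint on non-carriers). The row scale is the MAD-consistent robust
#' SD; for clean Gaussian rows all of this coincides with the classical
#' mean/SD convention. Samples with zero residual scale get z = 0
#' throughout. `n_components = "auto"` removes every component whose
#' (winsorized-matrix) variance share exceeds 0.7 / n_samples, the
#' relative threshold convention of depth-based exome CNV calling.
#'
#' @param dm a [depth_matrix()] (>= 2 samples and >= 2 targets).
#' @param n_components integer count of components to remove, or `"auto"`.
#' @param log_depth normalize `log1p(depth)` instead of raw depth
#'   (off by default, matching the raw-depth convention).
#' @return An object of class `norm_depth_matrix`: `targets`, `samples`,
#'   `z` (samples x targets) and `n_components_removed`.
#' @export
normalize_depth <- function(dm, n_components = "auto", log_depth = FALSE) {
  X <- dm$depth
  if (nrow(X) < 2L || ncol(X) < 2L) stopf("need >= 2 samples and >= 2 targets")
  if (log_depth) X <- log1p(X)
  Xc <- sweep(X, 2L, apply(X, 2L, mean, trim = 0.2))
  # winsorized copy for component estimation and projection: limit each
  # column at 2 column-MADs (fallback to the column SD where the MAD
  # degenerates)
  cs <- apply(Xc, 2L, mad)
  cs0 <- apply(Xc, 2L, sd)
  cs <- ifelse(cs > 0, cs, cs0)
  lim <- matrix(rep(ifelse(cs > 0, 2 * cs, Inf), each = nrow(Xc)),
                nrow = nrow(Xc))
  W <- pmin(pmax(Xc, -lim), lim)
  sv <- svd(W)
  ev <- sv$d^2
  total <- sum(ev)
  if (identical(n_components, "auto")) {
    k <- if (total == 0) 0L else sum(ev / total > 0.7 / nrow(X))
  } else {
    k <- as.integer(n_components)
    if (k >= min(dim(X))) stopf("n_components must be < min(n_samples, n_targets)")
  }
  R <- Xc
  if (k > 0L) {
    Uk <- sv$u[, seq_len(k), drop = FALSE]
    R <- Xc - Uk %*% (t(Uk) %*% W)
  }
  mu <- rowMeans(R)
  sdev <- apply(R, 1L, function(x) mad(x, center = mean(x)))
  # rows whose residual scale is negligible relative to the data (exact
  # low-rank input, constant samples) carry no copy-number information
  tiny <- max(1e-12, 1e-8 * mean(abs(X)))
  z <- (R - mu) / ifelse(sdev > tiny, sdev, 1)
  z[sdev <= tiny, ] <- 0
  dimnames(z) <- list(dm$samples, NULL)
  structure(list(targets = dm$targets, samples = dm$samples, z = z,
                 n_components_removed = k),
            class = "norm_depth_matrix")
}

#' HMM parameters for depth-based CNV genotyping
#'
#' Numeric defaults follow the conventions of depth-based exome CNV
#' calling: emission means at -3 / +3 z for deletion / duplication, unit
#' emission SD, a 1e-4 per-target prior of entering a CNV state, and an
#' expected dwell of 6 targets (geometric run length).
#'
#' @param p_cnv per-target probability of transitioning diploid -> CNV
#'   (each direction); must be in (0, 0.5).
#' @param mean_targets_per_cnv expected CNV run length in targets (>= 1).
#' @param del_mean,dup_mean Gaussian emission means (z units) for the
#'   deletion and duplication states; the diploid state emits mean 0.
#' @param emission_sd common Gaussian emission SD (z units).
#' @return A `hmm_params` list.
#' @export
hmm_params <- function(p_cnv = 1e-4, mean_targets_per_cnv = 6,
                       del_mean = -3, dup_mean = 3, emission_sd = 1) {
  assert_scalar_num(p_cnv, "p_cnv", min = 1e-12, max = 0.5 - 1e-12)
  assert_scalar_num(mean_targets_per_cnv, "mean_targets_per_cnv", min = 1)
  structure(list(p_cnv = p_cnv, mean_targets_per_cnv = mean_targets_per_cnv,
                 del_mean = del_mean, dup_mean = dup_mean,
                 emission_sd = emission_sd),
            class = "hmm_params")
}

# State order throughout: 1 = DEL, 2 = DIPLOID, 3 = DUP.
hmm_matrices <- function(params) {
  p <- params$p_cnv
  q <- 1 / params$mean_targets_per_cnv
  A <- rbind(
    c(1 - q, q * (1 - p), q * p),
    c(p, 1 - 2 * p, p),
    c(q * p, q * (1 - p), 1 - q)
  )
  list(logA = log(A), logpi = log(c(p, 1 - 2 * p, p)),
       means = c(params$del_mean, 0, params$dup_mean), sd = params$emission_sd)
}

hmm_loglik <- function(z, m) {
  # T x 3 matrix of Gaussian log emission densities
  outer(z, m$means, function(x, mu) stats::dnorm(x, mu, m$sd, log = TRUE))
}

#' Viterbi decoding of a z-score track
#'
#' @param z numeric vector of normalized depth z-scores for one sample on
#'   one chromosome (ordered by target).
#' @param params a [hmm_params()].
#' @return Integer vector of states (1 = DEL, 2 = diploid, 3 = DUP).
#' @export
hmm_viterbi <- function(z, params = hmm_params()) {
  if (any(!is.finite(z))) stopf("non-finite z-scores in HMM input")
  m <- hmm_matrices(params)
  Tn <- length(z)
  ll <- hmm_loglik(z, m)
  delta <- m$logpi + ll[1L, ]
  psi <- matrix(0L, nrow = Tn, ncol = 3L)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + m$logA            # 3x3: prev state x next state
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], 1:3)] + ll[t, ]
    }
  }
  states <- integer(Tn)
  states[Tn] <- which.max(delta)
  if (Tn > 1L) for (t in (Tn - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  states
}

#' Forward-backward state posteriors for a z-score track
#'
#' @inheritParams hmm_viterbi
#' @return T x 3 matrix of posterior state probabilities.
#' @export
hmm_posterior <- function(z, params = hmm_params()) {
  m <- hmm_matrices(params)
  Tn <- length(z)
  ll <- hmm_loglik(z, m)
  A <- exp(m$logA)
  alpha <- matrix(0, Tn, 3L)
  cscale <- numeric(Tn)
  a <- exp(m$logpi + ll[1L, ])
  cscale[1L] <- sum(a)
  alpha[1L, ] <- a / cscale[1L]
  if (Tn > 1L) for (t in 2:Tn) {
    a <- (alpha[t - 1L, ] %*% A) * exp(ll[t, ])
    cscale[t] <- sum(a)
    alpha[t, ] <- a / cscale[t]
  }
  beta <- matrix(1, Tn, 3L)
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    b <- A %*% (exp(ll[t + 1L, ]) * beta[t + 1L, ])
    beta[t, ] <- b / cscale[t + 1L]
  }
  g <- alpha * beta
  g / rowSums(g)
}

#' Call CNVs per sample with the three-state HMM
#'
#' For each sample and chromosome the ordered target z-scores are Viterbi
#' decoded; consecutive targets assigned the same non-diploid state are
#' merged into one call. Call quality is the mean forward-backward
#' posterior of the call state over its spanned targets. Two standard QC
#' screens are applied to the merged segments: calls below `min_quality`
#' and calls spanning fewer than `min_targets` targets are dropped (the
#' posterior-quality and minimum-span filters of depth-based exome
#' callers, which remove marginal single-target excursions from
#' heavy-tailed depth noise); set both to their permissive values to keep
#' every Viterbi segment. Call coordinates run from the first spanned
#' target's start to the last one's end (target-resolution breakpoints).
#'
#' @param ndm a `norm_depth_matrix` from [normalize_depth()].
#' @param params a [hmm_params()].
#' @param min_quality minimum mean state posterior for a call to be
#'   reported (default 0.9; 0 disables the screen).
#' @param min_targets minimum spanned targets per call (default 2;
#'   1 disables the screen).
#' @return data.frame of calls: `sample`, `chrom`, `start`, `end`, `state`
#'   ("DEL"/"DUP"), `n_targets`, `mean_z`, `quality`, plus the spanned
#'   target index range `target_first`/`target_last` (into `ndm$targets`).
#' @export
call_cnvs_hmm <- function(ndm, params = hmm_params(), min_quality = 0.9,
                          min_targets = 2L) {
  if (any(!is.finite(ndm$z))) stopf("non-finite z-scores")
  tg <- ndm$targets
  out <- vector("list", 64L); n_out <- 0L
  for (ch in unique(tg$chrom)) {
    idx <- which(tg$chrom == ch)
    for (s in seq_along(ndm$samples)) {
      z <- ndm$z[s, idx]
      states <- hmm_viterbi(z, params)
      if (all(states == 2L)) next
      post <- hmm_posterior(z, params)
      r <- rle(states)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values != 2L)) {
        span <- starts[j]:ends[j]
        st <- r$values[j]
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- data.frame(
          sample = ndm$samples[s], chrom = ch,
          start = tg$start[idx[span[1L]]], end = tg$end[idx[span[length(span)]]],
          state = if (st == 1L) "DEL" else "DUP",
          n_targets = length(span), mean_z = mean(z[span]),
          quality = mean(post[span, st]),
          target_first = idx[span[1L]], target_last = idx[span[length(span)]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_out == 0L)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), state = character(0),
                      n_targets = integer(0), mean_z = numeric(0),
                      quality = numeric(0), target_first = integer(0),
                      target_last = integer(0)))
  calls <- do.call(rbind, out[seq_len(n_out)])
  calls <- calls[calls$quality >= min_quality & calls$n_targets >= min_targets,
                 , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Merge per-sample CNV calls into a cross-sample region catalog
#'
#' Calls overlapping on the same chromosome (union-overlap, regardless of
#' state) are merged into one CNV region; a region may therefore carry both
#' deletion and duplication carriers, as observed in real panels.
#'
#' @param calls data.frame of calls from [call_cnvs_hmm()].
#' @return A list of class `cnv_region_catalog`: `regions` (data.frame
#'   `region_id`, `chrom`, `start`, `end`, `n_del_carriers`,
#'   `n_dup_carriers`) and `carriers` (data.frame `region_id`, `sample`,
#'   `state`).
#' @export
cnv_regions <- function(calls) {
  empty <- list(
    regions = data.frame(region_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         n_del_carriers = integer(0), n_dup_carriers = integer(0)),
    carriers = data.frame(region_id = character(0), sample = character(0),
                          state = character(0)))
  class(empty) <- "cnv_region_catalog"
  if (nrow(calls) == 0L) return(empty)
  gr <- as_granges0(calls)
  red <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, red)
  rid <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  regions <- regions[order(match(regions$chrom, unique(calls$chrom)), regions$start), ]
  # stable region ids in genome order
  key_old <- paste(as.character(GenomicRanges::seqnames(red)),
                   GenomicRanges::start(red) - 1L)
  remap <- match(key_old, paste(regions$chrom, regions$start))
  rid <- remap[rid]
  regions$region_id <- sprintf("cnvr_%04d", seq_len(nrow(regions)))
  carriers <- unique(data.frame(region_id = regions$region_id[rid],
                                sample = calls$sample, state = calls$state,
                                stringsAsFactors = FALSE))
  regions$n_del_carriers <- vapply(regions$region_id, function(r)
    length(unique(carriers$sample[carriers$region_id == r & carriers$state == "DEL"])),
    integer(1))
  regions$n_dup_carriers <- vapply(regions$region_id, function(r)
    length(unique(carriers$sample[carriers$region_id == r & carriers$state == "DUP"])),
    integer(1))
  rownames(regions) <- NULL
  out <- list(regions = regions[, c("region_id", "chrom", "start", "end",
                                    "n_del_carriers", "n_dup_carriers")],
              carriers = carriers)
  class(out) <- "cnv_region_catalog"
  out
}

#' @export
print.cnv_region_catalog <- function(x, ...) {
  cat(sprintf("cnv_region_catalog: %d regions, %d carrier records\n",
              nrow(x$regions), nrow(x$carriers)))
  invisible(x)
}

#' Per-cluster CNV region frequencies and private CNVs
#'
#' Frequency = carriers-in-cluster / cluster size, per state and combined.
#' A region is private to a cluster iff all its carriers belong to it.
#'
#' @param catalog a [cnv_regions()] catalog.
#' @param popmap data.frame `sample`, `cluster`.
#' @return data.frame with one row per region x cluster (`region_id`,
#'   `cluster`, `freq_del`, `freq_dup`, `freq_any`) plus a `private_to`
#'   column on the per-region attribute frame `attr(, "regions")`
#'   (`region_id`, `private_to` = cluster label or NA).
#' @export
cnv_frequencies <- function(catalog, popmap) {
  carr <- catalog$carriers
  unknown <- setdiff(carr$sample, popmap$sample)
  if (length(unknown)) stopf("carrier samples missing from popmap: %s",
                             paste(head(unknown, 3), collapse = ", "))
  clusters <- sort(unique(popmap$cluster))
  csize <- table(popmap$cluster)
  carr$cluster <- popmap$cluster[match(carr$sample, popmap$sample)]
  grid <- expand.grid(region_id = catalog$regions$region_id, cluster = clusters,
                      stringsAsFactors = FALSE)
  count_in <- function(state) {
    sub <- if (is.null(state)) carr else carr[carr$state == state, ]
    # distinct carrier samples per region x cluster
    k <- table(factor(sub$region_id, levels = catalog$regions$region_id),
               factor(sub$cluster, levels = clusters))
    as.vector(k[cbind(match(grid$region_id, rownames(k)),
                      match(grid$cluster, colnames(k)))])
  }
  dedup <- unique(carr[, c("region_id", "sample", "cluster")])
  k_any <- table(factor(dedup$region_id, levels = catalog$regions$region_id),
                 factor(dedup$cluster, levels = clusters))
  grid$freq_del <- count_in("DEL") / as.numeric(csize[grid$cluster])
  grid$freq_dup <- count_in("DUP") / as.numeric(csize[grid$cluster])
  grid$freq_any <- as.vector(k_any[cbind(match(grid$region_id, rownames(k_any)),
                                         match(grid$cluster, colnames(k_any)))]) /
    as.numeric(csize[grid$cluster])
  priv <- vapply(catalog$regions$region_id, function(r) {
    cl <- unique(carr$cluster[carr$region_id == r])
    if (length(cl) == 1L) cl else NA_character_
  }, character(1))
  attr(grid, "regions") <- data.frame(region_id = catalog$regions$region_id,
                                      private_to = unname(priv),
                                      stringsAsFactors = FALSE)
  grid
}

#' Per-accession CNV burden and cluster comparisons
#'
#' Counts deletions and duplications per accession and summarizes call
#' lengths, then compares burden across clusters with a Kruskal-Wallis test
#' and pairwise Wilcoxon rank-sum tests with Holm correction.
#'
#' @param calls data.frame of calls from [call_cnvs_hmm()].
#' @param popmap data.frame `sample`, `cluster` (>= 2 non-empty clusters for
#'   the comparisons).
#' @param what which per-accession quantity drives the cluster comparison:
#'   total CNV count (default), deletion/duplication count, or median call
#'   length.
#' @return list with `per_accession` (sample, cluster, n_del, n_dup,
#'   mean_length, median_length), `kruskal` (htest), and `pairwise`
#'   (data.frame cluster_a, cluster_b, p_holm).
#' @export
cnv_burden <- function(calls, popmap,
                       what = c("n_cnv", "n_del", "n_dup", "median_length")) {
  what <- match.arg(what)
  per <- data.frame(sample = popmap$sample, cluster = popmap$cluster,
                    stringsAsFactors = FALSE)
  per$n_del <- vapply(per$sample, function(s)
    sum(calls$sample == s & calls$state == "DEL"), integer(1))
  per$n_dup <- vapply(per$sample, function(s)
    sum(calls$sample == s & calls$state == "DUP"), integer(1))
  lens <- calls$end - calls$start
  per$mean_length <- vapply(per$sample, function(s) {
    l <- lens[calls$sample == s]; if (length(l)) mean(l) else NA_real_
  }, numeric(1))
  per$median_length <- vapply(per$sample, function(s) {
    l <- lens[calls$sample == s]; if (length(l)) median(l) else NA_real_
  }, numeric(1))
  keep <- names(which(table(per$cluster) > 0))
  if (length(keep) < length(unique(popmap$cluster)))
    warnf("empty clusters excluded from burden comparison")
  y <- switch(what, n_cnv = per$n_del + per$n_dup, n_del = per$n_del,
              n_dup = per$n_dup, median_length = per$median_length)
  ok <- per$cluster %in% keep & !is.na(y)
  kw <- NULL; pw <- NULL
  if (length(unique(per$cluster[ok])) >= 2L) {
    kw <- kruskal.test(y[ok], factor(per$cluster[ok]))
    cl <- sort(unique(per$cluster[ok]))
    pairs <- t(combn(cl, 2L))
    praw <- apply(pairs, 1L, function(pr)
      suppressWarnings(wilcox.test(y[ok & per$cluster == pr[1]],
                                   y[ok & per$cluster == pr[2]])$p.value))
    pw <- data.frame(cluster_a = pairs[, 1], cluster_b = pairs[, 2],
                     p_holm = p.adjust(praw, method = "holm"),
                     stringsAsFactors = FALSE)
  }
  list(per_accession = per, kruskal = kw, pairwise = pw)
}

#' CNV count vs chromosome size and gene count (Spearman)
#'
#' @param catalog a [cnv_regions()] catalog.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param gene_counts named numeric vector of per-chromosome gene counts.
#' @return data.frame with rows `size` and `gene_count`: Spearman `rho`
#'   and `p_value` for CNV-count association with each.
#' @export
cnv_chromosome_correlation <- function(catalog, chrom_sizes, gene_counts) {
  if (length(chrom_sizes) < 4L) stopf("need >= 4 chromosomes")
  counts <- table(factor(catalog$regions$chrom, levels = names(chrom_sizes)))
  tests <- lapply(list(size = chrom_sizes, gene_count = gene_counts[names(chrom_sizes)]),
                  function(x) suppressWarnings(
                    cor.test(as.numeric(counts), as.numeric(x), method = "spearman")))
  data.frame(
    against = names(tests),
    rho = vapply(tests, function(t) unname(t$estimate), numeric(1)),
    p_value = vapply(tests, function(t) t$p.value, numeric(1)),
    row.names = NULL
  )
}
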