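# Shared fixtures and independent oracle implementations. Oracles are
# deliberately written from first principles (enumeration, ANOVA sums,
# direct formulas) so they share no code path with the package.

toy_gm <- function(geno, chrom = "chr1", pos = NULL, qual = 1000,
                   mean_depth = 20, ref = "A", alt = "T") {
  geno <- as.matrix(geno)
  ns <- ncol(geno)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = ns)
  sites <- data.frame(chrom = rep_len(chrom, ns), pos = pos,
                      ref = rep_len(ref, ns), alt = rep_len(alt, ns),
                      qual = rep_len(qual, ns),
                      mean_depth = rep_len(mean_depth, ns))
  genotype_matrix(geno, sites, sprintf("S%02d", seq_len(nrow(geno))))
}

rand_gm <- function(n_samples, n_sites, seed, p_missing = 0,
                    maf_min = 0.05) {
  set.seed(seed)
  p <- runif(n_sites, maf_min, 1 - maf_min)
  geno <- sapply(p, function(pp) rbinom(n_samples, 2L, pp))
  if (p_missing > 0) geno[runif(length(geno)) < p_missing] <- NA
  toy_gm(geno)
}

# --- Tajima's D oracle: direct transcription of the 1989 quantities from
# a chromosome-level allele matrix ------------------------------------
oracle_tajima <- function(geno) {
  # expand genotypes into allele copies; per-site phase is irrelevant
  al <- rbind(ifelse(geno >= 1L, 1L, 0L), ifelse(geno == 2L, 1L, 0L))
  n <- nrow(al)
  seg <- apply(al, 2L, function(x) length(unique(x)) > 1L)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # pi: average pairwise differences across all chromosome pairs
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + sum(al[i, ] != al[j, ])
  ppi <- diffs / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (ppi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Weir-Cockerham oracle via the allele-indicator ANOVA decomposition
oracle_wc_site <- function(ga, gb) {
  pops <- list(ga[!is.na(ga)], gb[!is.na(gb)])
  n <- vapply(pops, length, numeric(1))
  if (any(n < 2)) return(c(a = NA, b = NA, c = NA))
  r <- 2
  p_i <- vapply(pops, function(g) mean(g) / 2, numeric(1))
  pbar <- sum(n * p_i) / sum(n)
  SSG <- sum(vapply(pops, function(g) sum(g == 1L) * 0.5, numeric(1)))
  SSI <- sum(vapply(seq_len(r), function(i)
    sum(2 * (pops[[i]] / 2 - p_i[i])^2), numeric(1)))
  SSP <- sum(2 * n * (p_i - pbar)^2)
  MSG <- SSG / sum(n)
  MSI <- SSI / sum(n - 1)
  MSP <- SSP / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# --- H12 brute force: squared pooled haplotype frequencies ------------
oracle_h12 <- function(haps) {
  f <- sort(table(haps) / length(haps), decreasing = TRUE)
  if (length(f) == 1L) return(unname(f[1]^2))
  unname((f[1] + f[2])^2 + sum(f[-(1:2)]^2))
}

# --- Viterbi brute force: enumerate all 3^T state paths ----------------
oracle_viterbi <- function(z, params) {
  Tn <- length(z)
  m <- lenspop:::hmm_matrices(params)
  ll <- outer(z, m$means, function(x, mu) dnorm(x, mu, m$sd, log = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:3), Tn)))
  lp <- apply(paths, 1L, function(st) {
    v <- m$logpi[st[1L]] + ll[1L, st[1L]]
    if (Tn > 1L) for (t in 2:Tn)
      v <- v + m$logA[st[t - 1L], st[t]] + ll[t, st[t]]
    v
  })
  as.integer(paths[which.max(lp), ])
}

# --- rarefaction by exhaustive subset enumeration ---------------------
# counts: copies per allele at one locus; returns expected distinct
# alleles in a subsample of g copies
oracle_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- combn(length(copies), g)
  mean(apply(subsets, 2L, function(ix) length(unique(copies[ix]))))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
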