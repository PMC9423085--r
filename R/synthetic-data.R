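# Synthetic-data generator: admixed selfing clusters with
# Balding-Nichols-dispersed allele frequencies, exact neutral allele-count
# placement, implanted low-frequency CNVs, batch-structured exome read
# depth, and optional selective sweeps. Every downstream module is
# exercised against datasets from here.

#' Configuration for the synthetic diversity panel
#'
#' Defaults describe a desk-scale selfing diversity panel: 8 clusters of
#' 12 accessions, 7 chromosomes of 10 Mb, 7000 SNPs, 3500 exome targets,
#' selfing rate 0.95, between-cluster F_ST 0.2, 22x mean coverage and 60
#' implanted CNVs with a low-frequency-skewed carrier frequency
#' distribution.
#'
#' @param n_clusters number of population clusters.
#' @param samples_per_cluster accessions per cluster.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_snps total SNP count (must be >= 50 per chromosome so that
#'   SNP-count windows are possible).
#' @param n_targets total exome-target count.
#' @param n_genes total annotated genes.
#' @param selfing_rate selfing fraction in \[0, 1\]; the equilibrium
#'   inbreeding coefficient used for genotype sampling is s / (2 - s).
#' @param fst_between_clusters Balding-Nichols dispersion of cluster
#'   allele frequencies around the ancestral frequency, in \[0, 1).
#' @param n_true_cnvs implanted CNVs (>= 0).
#' @param cnv_z_shift target |z| magnitude of a single-copy CNV after
#'   depth normalization; controls the default depth noise SD
#'   (0.5 / cnv_z_shift).
#' @param cnv_min_targets minimum targets spanned per CNV (>= 1).
#' @param n_batch_components low-rank multiplicative batch components in
#'   the depth model (>= 0).
#' @param base_depth mean coverage.
#' @param sweep_positions optional data.frame (`chrom`, `bp`) of selective
#'   sweep centers implanted in `sweep_cluster`.
#' @param sweep_cluster index (1-based) of the cluster carrying the sweeps.
#' @param sweep_width_bp span of each implanted sweep.
#' @param sweep_carrier_frac fraction of the sweep cluster carrying the
#'   swept haplotype.
#' @param depth_noise_sd log-scale depth noise SD; `NULL` = 0.5 / cnv_z_shift.
#' @param sample_effect_sd log-scale per-sample depth effect SD.
#' @param batch_sd log-scale SD of each batch component.
#' @param target_shape gamma shape (= rate) of the mean-1 per-target
#'   capture-efficiency effect.
#' @param cnv_category_bias optional `list(category =, multiplier =)`
#'   biasing CNV placement toward targets overlapping genes of one
#'   functional category.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   datasets byte for byte.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_clusters = 8L, samples_per_cluster = 12L,
                       n_chromosomes = 7L, chrom_length_bp = 1e7,
                       n_snps = 7000L, n_targets = 3500L, n_genes = 1050L,
                       selfing_rate = 0.95, fst_between_clusters = 0.2,
                       n_true_cnvs = 60L, cnv_z_shift = 3,
                       cnv_min_targets = 5L, n_batch_components = 2L,
                       base_depth = 22, sweep_positions = NULL,
                       sweep_cluster = 1L, sweep_width_bp = 4e5,
                       sweep_carrier_frac = 0.95, depth_noise_sd = NULL,
                       sample_effect_sd = 0.07, batch_sd = 0.1,
                       target_shape = 50, cnv_category_bias = NULL,
                       seed = 1L) {
  for (nm in c("n_clusters", "samples_per_cluster", "n_chromosomes",
               "chrom_length_bp", "n_snps", "n_targets", "n_genes"))
    assert_scalar_num(get(nm), nm, min = 1)
  assert_scalar_num(selfing_rate, "selfing_rate", min = 0, max = 1)
  assert_scalar_num(fst_between_clusters, "fst_between_clusters",
                    min = 0, max = 1 - 1e-9)
  assert_scalar_num(n_true_cnvs, "n_true_cnvs", min = 0)
  assert_scalar_num(cnv_min_targets, "cnv_min_targets", min = 1)
  assert_scalar_num(n_batch_components, "n_batch_components", min = 0)
  assert_scalar_num(base_depth, "base_depth", min = 0)
  # cnv_z_shift is the guaranteed minimum |z| of a single-copy change.
  # A single-copy change moves depth by a factor 0.5; the 0.3 numerator
  # absorbs the worst-case attenuation from carrier-frequency centering
  # (frequencies capped at 0.1) and below-average capture efficiency, so
  # the typical realized shift sits above the floor.
  if (is.null(depth_noise_sd)) depth_noise_sd <- 0.3 / cnv_z_shift
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the full synthetic dataset
#'
#' Ancestral derived-allele counts are drawn with neutral 1 / i weights;
#' with no between-cluster differentiation the count is split exactly
#' across clusters (multivariate hypergeometric), otherwise cluster
#' frequencies are Balding-Nichols-dispersed and per-cluster counts drawn
#' binomially. Within a cluster, derived copies are placed under the
#' selfing-equilibrium autozygosity structure so genotype homozygosity
#' matches the selfing rate while the allele count stays exact. Sweeps
#' fix one haplotype (homozygous derived across the sweep span) in a
#' fraction of the designated cluster. CNVs are implanted on contiguous
#' target runs with low-frequency-skewed Beta(0.5, 6) carrier
#' frequencies, dispersed across clusters by the same F_ST parameter.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_dataset` list: `genotypes` ([genotype_matrix()]),
#'   `depths` ([depth_matrix()]), `truth_cnvs` (list `cnvs`, `carriers`),
#'   `popmap`, `annotation` (list `genes`, `categories`),
#'   `truth_sweep_genes`, `chrom_lengths`, `config`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 50 * config$n_chromosomes)
    stopf("n_snps (%d) must be >= 50 per chromosome (%d needed)",
          config$n_snps, 50 * config$n_chromosomes)
  set.seed(derive_seed(config$seed, 0L))
  K <- config$n_clusters
  n_c <- config$samples_per_cluster
  N <- K * n_c
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(config$chrom_length_bp, length(chroms)), chroms)
  sample_ids <- sprintf("S%03d", seq_len(N))
  clusters <- sprintf("C%d", rep(seq_len(K), each = n_c))
  popmap <- data.frame(sample = sample_ids, cluster = clusters,
                       stringsAsFactors = FALSE)

  targets <- make_intervals(chroms, chrom_lengths, config$n_targets,
                            min_len = 120L, max_len = 400L)
  genes <- make_intervals(chroms, chrom_lengths, config$n_genes,
                          min_len = 2000L, max_len = 5000L)
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$resistance <- runif(nrow(genes)) < 0.02
  genes <- genes[, c("gene_id", "chrom", "start", "end", "resistance")]
  categories <- assign_categories(genes$gene_id)

  sites <- make_snp_sites(chroms, chrom_lengths, config$n_snps, genes)
  drift <- cluster_drift(config)
  geno <- simulate_genotypes(sites, popmap, config, drift)

  sweep_genes <- character(0)
  if (!is.null(config$sweep_positions) && nrow(config$sweep_positions) > 0) {
    sw <- implant_sweeps(geno, sites, popmap, config, genes)
    geno <- sw$geno
    sweep_genes <- sw$genes
  }

  truth_cnvs <- implant_cnvs(targets, popmap, config, genes, categories, drift)
  depths <- simulate_read_depth(truth_cnvs, targets, config,
                                sample_ids = sample_ids)

  gm <- genotype_matrix(geno, sites, sample_ids)
  structure(list(genotypes = gm, depths = depths, truth_cnvs = truth_cnvs,
                 popmap = popmap,
                 annotation = list(genes = genes, categories = categories),
                 truth_sweep_genes = sweep_genes,
                 chrom_lengths = chrom_lengths, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d samples in %d clusters, %d SNPs, ",
                     "%d targets, %d truth CNVs, %d sweep genes\n"),
              n_samples(x$genotypes), length(unique(x$popmap$cluster)),
              n_sites(x$genotypes), nrow(x$depths$targets),
              nrow(x$truth_cnvs$cnvs), length(x$truth_sweep_genes)))
  invisible(x)
}

# Evenly spaced non-overlapping intervals with random lengths.
make_intervals <- function(chroms, chrom_lengths, n_total, min_len, max_len) {
  per <- diff(round(seq(0, n_total, length.out = length(chroms) + 1L)))
  out <- lapply(seq_along(chroms), function(ci) {
    nt <- per[ci]
    if (nt == 0L) return(NULL)
    len <- chrom_lengths[[ci]]
    spacing <- floor(len / (nt + 1L))
    if (spacing <= max_len)
      stopf("chromosome %s too short for %d intervals of up to %d bp",
            chroms[ci], nt, max_len)
    starts <- spacing * seq_len(nt)
    widths <- as.integer(round(runif(nt, min_len, max_len)))
    data.frame(chrom = chroms[ci], start = starts,
               end = starts + widths, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Exome-capture SNPs concentrate in and around genes: 80% of positions
# are drawn inside a gene interval (plus a 1 kb flank), the rest
# uniformly.
make_snp_sites <- function(chroms, chrom_lengths, n_snps, genes) {
  per <- diff(round(seq(0, n_snps, length.out = length(chroms) + 1L)))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(chroms), function(ci) {
    g_ch <- genes[genes$chrom == chroms[ci], , drop = FALSE]
    n_ch <- per[ci]
    genic <- if (nrow(g_ch)) runif(n_ch) < 0.8 else rep(FALSE, n_ch)
    pos <- integer(n_ch)
    if (any(genic)) {
      gi <- sample.int(nrow(g_ch), sum(genic), replace = TRUE)
      lo <- pmax(1L, g_ch$start[gi] - 1000L)
      hi <- pmin(chrom_lengths[[ci]] - 1L, g_ch$end[gi] + 1000L)
      pos[genic] <- lo + floor(runif(sum(genic)) * (hi - lo + 1L))
    }
    pos[!genic] <- sample.int(chrom_lengths[[ci]] - 1L, sum(!genic))
    pos <- sort(unique(pos))
    while (length(pos) < n_ch) {
      extra <- sample.int(chrom_lengths[[ci]] - 1L, n_ch - length(pos))
      pos <- sort(unique(c(pos, extra)))
    }
    ref <- sample(bases, n_ch, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    data.frame(chrom = chroms[ci], pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  sites$qual <- round(runif(nrow(sites), 100, 3000))
  sites$mean_depth <- round(rgamma(nrow(sites), shape = 50, rate = 50 / 22), 2)
  rownames(sites) <- NULL
  sites
}

# MapMan-style functional vocabulary with decreasing prevalence.
category_vocab <- function() {
  c("Enzymes", "RNA biosynthesis", "Protein modification",
    "Solute transport", "Cell wall organization", "External stimuli response",
    "Nucleotide metabolism", "Photosynthesis", "Lipid metabolism",
    "Coenzyme metabolism", "Protein translocation", "Development")
}

assign_categories <- function(gene_ids) {
  vocab <- category_vocab()
  w <- 1 / seq_along(vocab)
  labelled <- runif(length(gene_ids)) > 0.08
  first <- sample(vocab, length(gene_ids), replace = TRUE, prob = w)
  second_draw <- sample(vocab, length(gene_ids), replace = TRUE, prob = w)
  has_second <- labelled & runif(length(gene_ids)) < 0.25 & second_draw != first
  cats <- rbind(
    data.frame(gene_id = gene_ids[labelled], category = first[labelled]),
    data.frame(gene_id = gene_ids[has_second], category = second_draw[has_second])
  )
  cats[order(cats$gene_id, cats$category), ]
}

# Exact-count genotype sampler under selfing-equilibrium autozygosity.
# Returns an integer genotype vector of length n_ind summing to k.
place_copies <- function(k, n_ind, F_is) {
  if (k <= 0L) return(integer(n_ind))
  if (k >= 2L * n_ind) return(rep(2L, n_ind))
  ibd <- runif(n_ind) < F_is
  if (k %% 2L == 1L && all(ibd)) {
    if (F_is >= 1) k <- k - 1L             # full selfing: keep homozygosity
    else ibd[sample.int(n_ind, 1L)] <- FALSE
    if (k == 0L) return(integer(n_ind))
  }
  M <- sum(ibd); U <- 2L * (n_ind - M)
  j_lo <- max(0L, as.integer(ceiling((k - U) / 2)))
  j_hi <- min(M, k %/% 2L)
  geno <- integer(n_ind)
  if (j_hi < j_lo) return(geno)            # unreachable in practice
  js <- j_lo:j_hi
  lw <- lchoose(M, js) + lchoose(U, k - 2L * js)
  j <- if (length(js) == 1L) js else
    sample(js, 1L, prob = exp(lw - max(lw)))
  ibd_idx <- which(ibd)
  if (j > 0L) geno[sample(ibd_idx, j)] <- 2L
  n_single <- k - 2L * j
  if (n_single > 0L) {
    slots <- sample.int(U, n_single)
    owner <- which(!ibd)[ceiling(slots / 2)]
    for (o in owner) geno[o] <- geno[o] + 1L
  }
  geno
}

# Per-cluster drift coefficients: real panels are differentiated
# hierarchically (a strongly drifted cluster is divergent from everyone),
# so each cluster gets its own Balding-Nichols F, log-normally spread
# around fst_between_clusters (mean-normalized so the parameter keeps its
# meaning). SNP and CNV frequency dispersion share these coefficients.
cluster_drift <- function(config) {
  Fst <- config$fst_between_clusters
  if (Fst == 0) return(rep(0, config$n_clusters))
  w <- exp(rnorm(config$n_clusters, 0, 0.5))
  pmin(0.9, Fst * w / mean(w))
}

simulate_genotypes <- function(sites, popmap, config, drift) {
  K <- config$n_clusters
  n_c <- config$samples_per_cluster
  N <- nrow(popmap)
  n_tot <- 2L * N
  F_is <- if (config$selfing_rate >= 1) 1 else
    config$selfing_rate / (2 - config$selfing_rate)
  Fst <- config$fst_between_clusters
  S <- nrow(sites)
  # neutral ancestral derived counts, weight 1/i
  i <- 1:(n_tot - 1L)
  k_global <- sample(i, S, replace = TRUE, prob = 1 / i)
  geno <- matrix(0L, nrow = N, ncol = S)
  cl_rows <- split(seq_len(N), popmap$cluster)[unique(popmap$cluster)]
  for (s in seq_len(S)) {
    k <- k_global[s]
    if (Fst == 0) {
      rem_n <- n_tot; rem_k <- k
      for (ci in seq_len(K)) {
        kc <- if (ci == K) rem_k else
          rhyper(1L, 2L * n_c, rem_n - 2L * n_c, rem_k)
        geno[cl_rows[[ci]], s] <- place_copies(kc, n_c, F_is)
        rem_n <- rem_n - 2L * n_c; rem_k <- rem_k - kc
      }
    } else {
      p <- k / n_tot
      shape <- (1 - drift) / drift
      pc <- rbeta(K, p * shape, (1 - p) * shape)
      for (ci in seq_len(K)) {
        kc <- rbinom(1L, 2L * n_c, pc[ci])
        geno[cl_rows[[ci]], s] <- place_copies(kc, n_c, F_is)
      }
    }
  }
  geno
}

implant_sweeps <- function(geno, sites, popmap, config, genes) {
  sw <- config$sweep_positions
  cl <- sprintf("C%d", config$sweep_cluster)
  rows <- which(popmap$cluster == cl)
  n_car <- max(1L, round(config$sweep_carrier_frac * length(rows)))
  gene_hits <- character(0)
  for (r in seq_len(nrow(sw))) {
    lo <- sw$bp[r] - config$sweep_width_bp / 2
    hi <- sw$bp[r] + config$sweep_width_bp / 2
    cols <- which(sites$chrom == sw$chrom[r] & sites$pos >= lo & sites$pos <= hi)
    if (!length(cols)) next
    carriers <- rows[sample.int(length(rows), n_car)]
    geno[carriers, cols] <- 2L
    win <- data.frame(chrom = sw$chrom[r], start = max(0, lo), end = hi)
    ov <- overlap_pairs0(win, genes)
    gene_hits <- c(gene_hits, genes$gene_id[ov$s_idx])
  }
  list(geno = geno, genes = sort(unique(gene_hits)))
}

implant_cnvs <- function(targets, popmap, config, genes, categories, drift) {
  n_cnv <- config$n_true_cnvs
  empty <- list(
    cnvs = data.frame(cnv_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), state = character(0),
                      target_first = integer(0), target_last = integer(0),
                      n_targets = integer(0)),
    carriers = data.frame(cnv_id = character(0), sample = character(0),
                          ratio = numeric(0)))
  if (n_cnv == 0L) return(empty)
  K <- config$n_clusters
  Fst <- config$fst_between_clusters
  used <- logical(nrow(targets))
  start_weight <- rep(1, nrow(targets))
  if (!is.null(config$cnv_category_bias)) {
    biased <- categories$gene_id[categories$category ==
                                   config$cnv_category_bias$category]
    hit <- overlaps_any0(targets, genes[genes$gene_id %in% biased, ])
    start_weight[hit] <- config$cnv_category_bias$multiplier
  }
  cnvs <- list(); carriers <- list()
  for (v in seq_len(n_cnv)) {
    L <- config$cnv_min_targets + min(rgeom(1L, 0.35), 8L)
    placed <- FALSE
    for (try in 1:200) {
      t0 <- sample.int(nrow(targets), 1L, prob = start_weight)
      span <- t0:min(t0 + L - 1L, nrow(targets))
      if (length(span) < L) next
      if (length(unique(targets$chrom[span])) > 1L) next
      if (any(used[span])) next
      used[span] <- TRUE; placed <- TRUE
      break
    }
    if (!placed) next
    state <- sample(c("DEL", "DUP"), 1L)
    # carrier frequencies are rare-variant skewed and capped: CNVs under
    # purifying selection stay at low population frequency, and the
    # depth-shift contract (cnv_z_shift) assumes the cross-sample target
    # mean is dominated by non-carriers
    f0 <- rbeta(1L, 0.5, 6)
    while (f0 > 0.1) f0 <- rbeta(1L, 0.5, 6)
    carr <- character(0)
    for (ci in seq_len(K)) {
      fc <- if (Fst > 0) {
        shape_c <- (1 - drift[ci]) / drift[ci]
        rbeta(1L, max(f0, 1e-3) * shape_c, max(1 - f0, 1e-3) * shape_c)
      } else f0
      rows <- popmap$sample[popmap$cluster == sprintf("C%d", ci)]
      carr <- c(carr, rows[runif(length(rows)) < fc])
    }
    if (!length(carr)) carr <- sample(popmap$sample, 1L)
    # keep realized carrier counts in the rare-variant regime the
    # frequency model promises (cluster-level dispersion can otherwise
    # push a nominally rare CNV past the trim capacity of the
    # normalization's column centering)
    max_carr <- max(1L, floor(0.15 * nrow(popmap)))
    if (length(carr) > max_carr) carr <- sample(carr, max_carr)
    # high selfing drives carriers to homozygosity: most carry two
    # altered copies (ratio 0 or 2), a minority are heterozygous
    ratio <- if (state == "DEL")
      ifelse(runif(length(carr)) < 0.9, 0, 0.5)
    else ifelse(runif(length(carr)) < 0.9, 2, 1.5)
    id <- sprintf("cnv_%03d", v)
    cnvs[[length(cnvs) + 1L]] <- data.frame(
      cnv_id = id, chrom = targets$chrom[span[1L]],
      start = targets$start[span[1L]], end = targets$end[span[length(span)]],
      state = state, target_first = span[1L], target_last = span[length(span)],
      n_targets = length(span), stringsAsFactors = FALSE)
    carriers[[length(carriers) + 1L]] <- data.frame(
      cnv_id = id, sample = carr, ratio = ratio, stringsAsFactors = FALSE)
  }
  if (!length(cnvs)) return(empty)
  list(cnvs = do.call(rbind, cnvs), carriers = do.call(rbind, carriers))
}

#' Simulate per-target read depth
#'
#' Multiplicative depth model: base depth x gamma-distributed per-target
#' capture efficiency x log-normal per-sample effect x low-rank
#' multiplicative batch structure x log-normal noise x the carrier's copy
#' ratio (DEL 0.5 or 0; DUP 1.5 or 2). Depth is non-negative and
#' deterministic given the config seed.
#'
#' @param truth_cnvs truth CNV list (`cnvs`, `carriers`) as produced by
#'   [simulate_populations()]; CNV boundaries must coincide with target
#'   boundaries.
#' @param targets data.frame `chrom`, `start`, `end` (sorted,
#'   non-overlapping per chromosome).
#' @param config a [sim_config()].
#' @param sample_ids sample ids; defaults to the config's panel layout.
#' @return A [depth_matrix()].
#' @export
simulate_read_depth <- function(truth_cnvs, targets, config,
                                sample_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(config$n_clusters *
                                             config$samples_per_cluster))
  cn <- truth_cnvs$cnvs
  if (nrow(cn)) {
    key_start <- paste(targets$chrom, targets$start)
    key_end <- paste(targets$chrom, targets$end)
    bad <- !(paste(cn$chrom, cn$start) %in% key_start) |
      !(paste(cn$chrom, cn$end) %in% key_end)
    if (any(bad))
      stopf("truth CNVs not aligned to target boundaries: %s",
            paste(head(cn$cnv_id[bad], 3), collapse = ", "))
  }
  set.seed(derive_seed(config$seed, 7L))
  n <- length(sample_ids); nt <- nrow(targets)
  teff <- rgamma(nt, shape = config$target_shape, rate = config$target_shape)
  logd <- matrix(rep(log(config$base_depth * teff), each = n), nrow = n)
  if (config$sample_effect_sd > 0)
    logd <- logd + rnorm(n, 0, config$sample_effect_sd)
  if (config$n_batch_components > 0) {
    # discrete batch membership (each component splits the samples into
    # two sequencing batches) keeps the multiplicative structure exactly
    # low-rank on the raw-depth scale, so PCA can remove it fully
    for (r in seq_len(config$n_batch_components)) {
      u <- config$batch_sd * sample(c(-1, 1), n, replace = TRUE)
      v <- rnorm(nt)
      logd <- logd + outer(u, v)
    }
  }
  if (config$depth_noise_sd > 0)
    logd <- logd + matrix(rnorm(n * nt, 0, config$depth_noise_sd), n, nt)
  depth <- exp(logd)
  if (nrow(cn)) {
    for (i in seq_len(nrow(cn))) {
      carr <- truth_cnvs$carriers[truth_cnvs$carriers$cnv_id == cn$cnv_id[i], ]
      rows <- match(carr$sample, sample_ids)
      span <- cn$target_first[i]:cn$target_last[i]
      depth[rows, span] <- depth[rows, span] * carr$ratio
    }
  }
  depth_matrix(targets, sample_ids, depth)
}

#' Write a synthetic dataset to standard formats
#'
#' Emits `snps.vcf` (VCFv4.2), `depth.tsv` (targets x samples),
#' `popmap.tsv`, `targets.bed`, `truth_cnvs.bed` (BED6+: state, carrier
#' count), `genes.bed` and `categories.tsv`. Files round-trip losslessly
#' through the package readers. Refuses to overwrite existing files
#' unless `force`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if needed).
#' @param force overwrite existing files?
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, directory, force = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(directory, "snps.vcf"),
    depth = file.path(directory, "depth.tsv"),
    popmap = file.path(directory, "popmap.tsv"),
    targets = file.path(directory, "targets.bed"),
    truth_cnvs = file.path(directory, "truth_cnvs.bed"),
    genes = file.path(directory, "genes.bed"),
    categories = file.path(directory, "categories.tsv")
  )
  if (!force && any(file.exists(paths)))
    stopf("output files exist in '%s'; use force = TRUE to overwrite", directory)
  write_vcf(dataset$genotypes, paths[["vcf"]])
  write_depth_tsv(dataset$depths, paths[["depth"]])
  write.table(dataset$popmap, paths[["popmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$depths$targets, paths[["targets"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  cn <- dataset$truth_cnvs$cnvs
  carr_n <- vapply(cn$cnv_id, function(id)
    sum(dataset$truth_cnvs$carriers$cnv_id == id), integer(1))
  write.table(data.frame(cn$chrom, cn$start, cn$end, cn$cnv_id, cn$state, carr_n),
              paths[["truth_cnvs"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- dataset$annotation$genes
  write.table(data.frame(g$chrom, g$start, g$end, g$gene_id),
              paths[["genes"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cats <- dataset$annotation$categories
  cats$resistance <- as.integer(g$resistance[match(cats$gene_id, g$gene_id)])
  write.table(cats, paths[["categories"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Precision and recall of CNV calls against implanted truth
#'
#' A call is matched to a truth (CNV, carrier) pair of the same sample
#' when their intervals reciprocally overlap by at least
#' `min_reciprocal_overlap` of each length. Precision = matched calls /
#' all calls; recall = matched truth pairs / all truth pairs.
#'
#' @param calls data.frame of calls from [call_cnvs_hmm()].
#' @param truth_cnvs truth list (`cnvs`, `carriers`) from
#'   [simulate_populations()].
#' @param min_reciprocal_overlap reciprocal overlap fraction (default 0.5).
#' @return list: `precision`, `recall`, `n_calls`, `n_truth`.
#' @export
cnv_recovery <- function(calls, truth_cnvs, min_reciprocal_overlap = 0.5) {
  tr <- merge(truth_cnvs$carriers, truth_cnvs$cnvs, by = "cnv_id")
  n_truth <- nrow(tr); n_calls <- nrow(calls)
  if (n_truth == 0L || n_calls == 0L)
    return(list(precision = NA_real_, recall = NA_real_,
                n_calls = n_calls, n_truth = n_truth))
  ov <- overlap_pairs0(calls[, c("chrom", "start", "end")],
                       tr[, c("chrom", "start", "end")])
  ov <- ov[calls$sample[ov$q_idx] == tr$sample[ov$s_idx], , drop = FALSE]
  if (nrow(ov)) {
    w <- pmin(calls$end[ov$q_idx], tr$end[ov$s_idx]) -
      pmax(calls$start[ov$q_idx], tr$start[ov$s_idx])
    ok <- w >= min_reciprocal_overlap * (calls$end[ov$q_idx] - calls$start[ov$q_idx]) &
      w >= min_reciprocal_overlap * (tr$end[ov$s_idx] - tr$start[ov$s_idx])
    ov <- ov[ok, , drop = FALSE]
  }
  list(precision = length(unique(ov$q_idx)) / n_calls,
       recall = length(unique(ov$s_idx)) / n_truth,
       n_calls = n_calls, n_truth = n_truth)
}
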