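# Tajima's D windows, H12 scan and peaks, PCA outliers, consensus and
# gene mapping.

test_that("Tajima's D handles degenerate windows and the pi = theta case", {
  # monomorphic cluster: no segregating sites -> missing
  gm0 <- toy_gm(matrix(0L, 6, 5), pos = seq(1e4, 5e4, by = 1e4))
  pm <- data.frame(sample = gm0$sample_ids, cluster = "C")
  w0 <- tajimas_d_windows(gm0, pm, "C", window = 1e5,
                          chrom_lengths = c(chr1 = 1e5))
  expect_true(all(is.na(w0$value)))
  expect_error(tajimas_d_windows(gm0, pm[1:3, ], "C"), "< 4 samples")
})

test_that("windowed Tajima's D matches the direct-formula oracle", {
  set.seed(21)
  for (rep in 1:25) {
    gm <- rand_gm(20, 100, seed = 500 + rep)
    pm <- data.frame(sample = gm$sample_ids, cluster = "C")
    win <- tajimas_d_windows(gm, pm, "C", window = 2e5,
                             chrom_lengths = c(chr1 = 2e5))
    want <- oracle_tajima(gm$geno)
    expect_equal(win$value[1], want, tolerance = 1e-10)
  }
})

test_that("H12 closed forms and the brute-force tally agree", {
  # identical haplotypes
  gm_same <- toy_gm(matrix(2L, 5, 50))
  h <- suppressWarnings(h12_scan(gm_same, window_snps = 50, step_snps = 5))
  expect_equal(h$h12[1], 1.0)
  # all distinct haplotypes among 5 samples: (2/5)^2 + 3 (1/5)^2 = 0.28
  set.seed(31)
  geno <- matrix(0L, 5, 50)
  for (i in 1:5) geno[i, ] <- as.integer(rbinom(50, 1, 0.5) * 2L)
  while (anyDuplicated(apply(geno, 1, paste, collapse = "")))
    geno[1, ] <- as.integer(rbinom(50, 1, 0.5) * 2L)
  h2 <- suppressWarnings(h12_scan(toy_gm(geno), 50, 5))
  expect_equal(h2$h12[1], 0.28)
  # frequencies {0.5, 0.3, 0.2} over 10 samples
  base <- rbind(matrix(0L, 1, 50),
                matrix(2L, 1, 50),
                matrix(rep(c(0L, 2L), 25), 1, 50))
  geno3 <- base[c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3), ]
  h3 <- suppressWarnings(h12_scan(toy_gm(geno3), 50, 5))
  expect_equal(h3$h12[1], 0.68)
  # random windows against the oracle
  for (rep in 1:30) {
    set.seed(600 + rep)
    g <- matrix(sample(c(0L, 2L), 12 * 50, TRUE), 12, 50)
    h4 <- suppressWarnings(h12_scan(toy_gm(g), 50, 50))
    haps <- apply(ifelse(g == 2L, 1L, 0L), 1, paste, collapse = "")
    expect_equal(h4$h12[1], oracle_h12(haps), tolerance = 1e-12)
  }
})

test_that("heterozygous and missing-heavy pseudo-haplotypes are handled", {
  geno <- matrix(2L, 6, 50)
  geno[1, 1:30] <- 1L            # > 20% het -> dropped
  geno[2, 3] <- 1L               # lone het -> filled with major allele
  h <- suppressWarnings(h12_scan(toy_gm(geno), 50, 5))
  expect_equal(h$n_haplotypes[1], 5L)
  expect_equal(h$h12[1], 1.0)    # the fill makes all retained rows identical
  # chromosomes with < window SNPs are skipped with a warning
  expect_warning(h12_scan(toy_gm(matrix(0L, 4, 10)), 50, 5), "skipped")
})

test_that("peak finding thresholds, trims short peaks and ranks by height", {
  track <- data.frame(
    chrom = "chr1",
    start = seq(0, by = 2e4, length.out = 60),
    end = seq(0, by = 2e4, length.out = 60) + 1.9e5,
    center_bp = seq(1e5, by = 2e4, length.out = 60),
    n_haplotypes = 50,
    h12 = rep(0.05, 60))
  track$h12[10:20] <- 0.6                  # long peak (span > 150 kb)
  p1 <- find_peaks(track, threshold = 0.3)
  expect_equal(nrow(p1), 1L)
  expect_gt(p1$end - p1$start, 150000)
  # short run: span below the length cutoff is discarded
  track2 <- track; track2$h12 <- 0.05
  track2$end <- track2$start + 1e4
  track2$h12[10] <- 0.6
  expect_equal(nrow(find_peaks(track2, threshold = 0.3)), 0L)
  # more than top_k qualifying peaks: keep the top 5 by max height
  track3 <- track
  for (i in 0:6) track3$h12[1 + i * 8 + 0:2] <- 0.4 + i * 0.05
  p3 <- find_peaks(track3, threshold = 0.3, top_k = 5)
  expect_lte(nrow(p3), 5L)
  expect_equal(p3$max_h12, sort(p3$max_h12, decreasing = TRUE))
  # peaks are disjoint
  if (nrow(p3) > 1) {
    o <- p3[order(p3$start), ]
    expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
  }
  expect_equal(nrow(find_peaks(track[0, ])), 0L)
})

test_that("the outlier scan is calibrated under the null and finds spikes", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 20, n_chromosomes = 2,
                    chrom_length_bp = 2e7, n_snps = 4000, n_targets = 100,
                    n_genes = 60, n_true_cnvs = 0, fst_between_clusters = 0.15,
                    seed = 5)
  ds <- simulate_populations(cfg)
  macf <- filter_params(min_quality = 0, min_mean_depth = 0,
                        max_missingness = 1, min_allele_count = 10)
  sc <- pca_outlier_scan(filter_variants(ds$genotypes, macf), n_pcs = 2)
  frac <- mean(sc$snps$p_value < 0.01)
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.03)
  # spiked SNPs with a strong cluster-specific frequency shift
  gm <- ds$genotypes
  set.seed(99)
  spike <- sample(n_sites(gm), 40)
  p_by <- c(C1 = 0.95, C2 = 0.05, C3 = 0.05)
  for (j in spike)
    gm$geno[, j] <- as.integer(rbinom(nrow(gm$geno), 1,
                                      p_by[ds$popmap$cluster]) * 2L)
  sc2 <- pca_outlier_scan(filter_variants(gm, macf), n_pcs = 2)
  hit <- na.omit(match(paste(gm$sites$chrom[spike], gm$sites$pos[spike]),
                       paste(sc2$snps$chrom, sc2$snps$pos)))
  expect_gte(mean(sc2$snps$flagged[hit]), 0.8)
  # alpha = 0 flags nothing
  sc0 <- pca_outlier_scan(filter_variants(gm, macf), n_pcs = 2, alpha = 0)
  expect_equal(sum(sc0$snps$flagged), 0L)
  expect_error(pca_outlier_scan(gm, n_pcs = 0), "n_pcs")
})

test_that("consensus keeps genes seen by enough methods", {
  sets <- list(m1 = c("g1", "g2"), m2 = c("g2", "g3"), m3 = "g4")
  expect_equal(as.character(consensus_candidates(sets, 2)), "g2")
  expect_equal(as.character(consensus_candidates(sets, 1)),
               sort(c("g1", "g2", "g3", "g4")))
  expect_equal(length(consensus_candidates(list(a = "x", b = "y", c = "z"), 2)), 0L)
  expect_error(consensus_candidates(sets[1], 2), "exceeds")
  rep_ <- attr(consensus_candidates(sets, 2), "report")
  expect_equal(unname(rep_$per_method), c(2L, 2L, 1L))
})

test_that("interval and SNP hits map to overlapping genes", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(1000L, 5000L, 0L), end = c(2000L, 6000L, 500L))
  peak <- data.frame(chrom = "chr1", start = 900L, end = 5500L)
  expect_equal(regions_to_genes(peak, ann), c("g1", "g2"))
  snp_in <- data.frame(chrom = "chr1", pos = 1500L)
  expect_equal(regions_to_genes(snp_in, ann), "g1")
  snp_out <- data.frame(chrom = "chr1", pos = 3000L)
  expect_equal(regions_to_genes(snp_out, ann), character(0))
  expect_equal(regions_to_genes(snp_out, ann, flank_bp = 1500), "g1")
  expect_equal(regions_to_genes(snp_out, ann, flank_bp = 2500), c("g1", "g2"))
})

test_that("an implanted sweep reaches the two-method consensus", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 20, n_chromosomes = 2,
                    chrom_length_bp = 1e7, n_snps = 3000, n_targets = 200,
                    n_genes = 200, n_true_cnvs = 5, fst_between_clusters = 0.15,
                    sweep_positions = data.frame(chrom = "chr1", bp = 5e6),
                    sweep_width_bp = 4e5, seed = 2)
  ds <- simulate_populations(cfg)
  h12 <- suppressWarnings(h12_scan(ds$genotypes))
  peaks <- find_peaks(h12)
  g1 <- regions_to_genes(data.frame(chrom = peaks$chrom,
                                    start = peaks$start - 1L, end = peaks$end),
                         ds$annotation$genes)
  gm2 <- filter_variants(ds$genotypes, filter_params(
    min_quality = 0, min_mean_depth = 0, max_missingness = 1,
    min_allele_count = 10, min_distance_bp = 2000))
  sc <- pca_outlier_scan(gm2, n_pcs = 2)
  g2 <- regions_to_genes(sc$snps[sc$snps$flagged, c("chrom", "pos")],
                         ds$annotation$genes)
  cons <- consensus_candidates(list(h12 = g1, pca_outlier = g2), 2)
  expect_gt(length(ds$truth_sweep_genes), 0)
  expect_true(any(ds$truth_sweep_genes %in% cons))
})
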