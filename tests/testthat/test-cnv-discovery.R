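# Target filtering, depth normalization, the three-state HMM, region
# merging, frequencies, burden and chromosome correlations.

mk_dm <- function(depth, chrom = "chr1") {
  nt <- ncol(depth)
  depth_matrix(data.frame(chrom = rep_len(chrom, nt),
                          start = seq(0L, by = 500L, length.out = nt),
                          end = seq(0L, by = 500L, length.out = nt) + 200L),
               sprintf("S%02d", seq_len(nrow(depth))), depth)
}

test_that("target filtering drops short, shallow and saturated targets", {
  depth <- matrix(20, nrow = 4, ncol = 6)
  depth[, 3] <- 1       # mean depth below 3
  depth[, 5] <- 3500    # above 3000
  dm <- mk_dm(depth)
  dm$targets$end[2] <- dm$targets$start[2] + 80L   # 80 bp target
  out <- filter_targets(dm)
  expect_equal(nrow(out$targets), 3L)
  expect_equal(setdiff(seq_len(6), match(out$targets$start, dm$targets$start)),
               c(2, 3, 5))
  expect_error(filter_targets(mk_dm(matrix(1, 2, 3))), "all targets")
})

test_that("normalization sends constant and exact low-rank input to zero", {
  cm <- mk_dm(matrix(5, nrow = 5, ncol = 30))
  z <- normalize_depth(cm, n_components = 1)$z
  expect_true(all(z == 0))
  set.seed(1)
  u <- 1:6; v <- runif(40, 0.5, 2)
  rk1 <- mk_dm(outer(u, v))
  z1 <- normalize_depth(rk1, n_components = 1)$z
  expect_lt(max(abs(z1)), 1e-8)
  expect_error(normalize_depth(rk1, n_components = 6), "n_components")
})

test_that("auto component selection removes the simulated batch structure", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 12, n_chromosomes = 1,
                    chrom_length_bp = 5e6, n_snps = 100, n_targets = 600,
                    n_genes = 30, n_true_cnvs = 0, n_batch_components = 2,
                    seed = 7)
  ds <- simulate_populations(cfg)
  ndm <- normalize_depth(ds$depths)
  expect_gte(ndm$n_components_removed, 2L)
  # z-scoring convention: every sample row is centered
  expect_lt(max(abs(rowMeans(ndm$z))), 1e-6)
})

test_that("HMM decodes obvious tracks and ignores flat ones", {
  expect_equal(hmm_viterbi(rep(0, 20)), rep(2L, 20))
  z <- c(rep(0, 5), rep(-4, 5), rep(0, 5))
  st <- hmm_viterbi(z)
  expect_equal(st, c(rep(2L, 5), rep(1L, 5), rep(2L, 5)))
  ndm <- structure(list(
    targets = data.frame(chrom = "chr1",
                         start = seq(0L, by = 500L, length.out = 15),
                         end = seq(0L, by = 500L, length.out = 15) + 200L),
    samples = "S1", z = matrix(z, nrow = 1),
    n_components_removed = 0L), class = "norm_depth_matrix")
  calls <- call_cnvs_hmm(ndm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "DEL")
  expect_equal(calls$n_targets, 5L)
  expect_lt(calls$mean_z, 0)
  expect_gt(calls$quality, 0.9)
  # all-zero input produces no calls
  ndm$z[] <- 0
  expect_equal(nrow(call_cnvs_hmm(ndm)), 0L)
  expect_error(hmm_viterbi(c(0, NA, 1)), "finite")
})

test_that("Viterbi equals exhaustive path enumeration on short tracks", {
  set.seed(42)
  params <- hmm_params(p_cnv = 0.01, mean_targets_per_cnv = 3)
  for (i in 1:60) {
    Tn <- sample(2:6, 1)
    z <- rnorm(Tn, 0, 2.5)
    expect_equal(hmm_viterbi(z, params), oracle_viterbi(z, params))
  }
})

test_that("unfiltered call spans conserve the Viterbi state assignments", {
  set.seed(3)
  z <- matrix(rnorm(4 * 60), nrow = 4)
  z[2, 10:14] <- -5; z[3, 30:36] <- 5; z[4, 50] <- -6
  ndm <- structure(list(
    targets = data.frame(chrom = "chr1",
                         start = seq(0L, by = 500L, length.out = 60),
                         end = seq(0L, by = 500L, length.out = 60) + 200L),
    samples = paste0("S", 1:4), z = z, n_components_removed = 0L),
    class = "norm_depth_matrix")
  calls <- call_cnvs_hmm(ndm, min_quality = 0, min_targets = 1L)
  n_from_calls <- sum(calls$n_targets)
  n_from_viterbi <- sum(vapply(1:4, function(s)
    sum(hmm_viterbi(z[s, ]) != 2L), numeric(1)))
  expect_equal(n_from_calls, n_from_viterbi)
})

test_that("region merging unions overlaps and mixes states", {
  calls <- data.frame(
    sample = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 1000L, 1400L, 0L),
    end = c(2000L, 2000L, 2600L, 500L),
    state = c("DEL", "DEL", "DUP", "DUP"),
    n_targets = c(2L, 2L, 2L, 1L), mean_z = c(-4, -4, 4, 4),
    quality = 1, target_first = 1L, target_last = 2L)
  cat1 <- cnv_regions(calls)
  expect_equal(nrow(cat1$regions), 2L)
  r1 <- cat1$regions[cat1$regions$chrom == "chr1", ]
  expect_equal(r1$start, 1000L)
  expect_equal(r1$end, 2600L)
  expect_equal(r1$n_del_carriers, 2L)
  expect_equal(r1$n_dup_carriers, 1L)
  # disjoint calls stay distinct
  calls$start <- c(0L, 5000L, 10000L, 0L); calls$end <- calls$start + 100L
  expect_equal(nrow(cnv_regions(calls)$regions), 4L)
})

test_that("frequencies and private flags follow cluster membership", {
  calls <- data.frame(
    sample = c("a", "b", "e"), chrom = "chr1",
    start = c(0L, 0L, 9000L), end = c(1000L, 1000L, 9500L),
    state = "DEL", n_targets = 1L, mean_z = -4, quality = 1,
    target_first = 1L, target_last = 1L)
  popmap <- data.frame(sample = letters[1:8],
                       cluster = rep(c("C1", "C2"), each = 4))
  freqs <- cnv_frequencies(cnv_regions(calls), popmap)
  r1 <- freqs[freqs$cluster == "C1" & freqs$region_id == "cnvr_0001", ]
  expect_equal(r1$freq_any, 0.5)
  priv <- attr(freqs, "regions")
  expect_equal(priv$private_to, c("C1", "C2"))
  expect_error(cnv_frequencies(cnv_regions(calls),
                               popmap[popmap$sample != "a", ]), "popmap")
  # carriers across two clusters are not private
  calls2 <- calls; calls2$sample <- c("a", "e", "f")
  calls2$start <- 0L; calls2$end <- 1000L
  expect_true(is.na(attr(cnv_frequencies(cnv_regions(calls2), popmap),
                         "regions")$private_to))
})

test_that("burden summaries and rank tests behave under null and shift", {
  # per-accession medians
  calls <- data.frame(sample = "a", chrom = "chr1",
                      start = c(0L, 50000L), end = c(10000L, 80000L),
                      state = c("DEL", "DUP"), n_targets = 2L,
                      mean_z = c(-4, 4), quality = 1,
                      target_first = 1L, target_last = 2L)
  pm <- data.frame(sample = c("a", "b"), cluster = c("C1", "C2"))
  b <- quiet(cnv_burden(calls, pm))
  expect_equal(b$per_accession$median_length[1], 20000)
  expect_equal(b$per_accession$n_del[1], 1L)
  # null calibration: one common count distribution across clusters
  set.seed(10)
  rej <- 0
  for (r in 1:60) {
    pm2 <- data.frame(sample = sprintf("s%02d", 1:30),
                      cluster = rep(c("C1", "C2", "C3"), each = 10))
    counts <- rpois(30, 5)
    calls2 <- data.frame(
      sample = rep(pm2$sample, counts), chrom = "chr1",
      start = 0L, end = 1000L, state = "DEL", n_targets = 1L,
      mean_z = -4, quality = 1, target_first = 1L, target_last = 1L)
    kw <- cnv_burden(calls2, pm2)$kruskal
    if (!is.null(kw) && kw$p.value < 0.01) rej <- rej + 1
  }
  expect_lte(rej / 60, 0.05)
  # power: one cluster with strongly shifted call lengths
  pm3 <- data.frame(sample = sprintf("s%02d", 1:90),
                    cluster = rep(c("C1", "C2", "C3"), each = 30))
  set.seed(11)
  lens <- c(runif(30, 60000, 80000), runif(60, 10000, 30000))
  calls3 <- data.frame(sample = pm3$sample, chrom = "chr1", start = 0L,
                       end = as.integer(lens), state = "DEL", n_targets = 1L,
                       mean_z = -4, quality = 1,
                       target_first = 1L, target_last = 1L)
  b3 <- cnv_burden(calls3, pm3, what = "median_length")
  p_c1 <- b3$pairwise$p_holm[b3$pairwise$cluster_a == "C1" |
                               b3$pairwise$cluster_b == "C1"]
  expect_true(all(p_c1 < 0.01))
})

test_that("chromosome-level Spearman correlations hit the closed cases", {
  sizes <- c(chr1 = 1e6, chr2 = 2e6, chr3 = 3e6, chr4 = 4e6, chr5 = 5e6)
  counts <- c(2L, 4L, 6L, 8L, 10L)   # proportional to size
  regions <- data.frame(
    region_id = sprintf("r%02d", seq_len(sum(counts))),
    chrom = rep(names(sizes), counts),
    start = 0L, end = 1000L, n_del_carriers = 1L, n_dup_carriers = 0L)
  catalog <- list(regions = regions, carriers = NULL)
  res <- cnv_chromosome_correlation(catalog, sizes, setNames(counts, names(sizes)))
  expect_equal(res$rho[res$against == "size"], 1)
  rev_counts <- setNames(rev(counts), names(sizes))
  res2 <- cnv_chromosome_correlation(catalog, sizes, rev_counts)
  expect_equal(res2$rho[res2$against == "gene_count"], -1)
  expect_error(cnv_chromosome_correlation(catalog, sizes[1:3], counts[1:3]),
               ">= 4")
})

test_that("implanted CNVs are recovered with high precision and recall", {
  cfg <- sim_config(n_clusters = 5, samples_per_cluster = 10, n_chromosomes = 4,
                    chrom_length_bp = 1e7, n_snps = 800, n_targets = 2000,
                    n_genes = 200, n_true_cnvs = 30, cnv_min_targets = 5,
                    n_batch_components = 2, seed = 1)
  ds <- simulate_populations(cfg)
  calls <- call_cnvs_hmm(normalize_depth(filter_targets(ds$depths)))
  r <- cnv_recovery(calls, ds$truth_cnvs)
  expect_gt(r$precision, 0.85)
  expect_gt(r$recall, 0.9)
})
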