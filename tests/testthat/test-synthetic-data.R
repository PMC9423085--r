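# The synthetic-data generator: determinism, selfing, differentiation,
# depth model structure, and file round trips.

small_cfg <- function(...) {
  defaults <- list(n_clusters = 3, samples_per_cluster = 10, n_chromosomes = 1,
                   chrom_length_bp = 5e6, n_snps = 300, n_targets = 100,
                   n_genes = 40, n_true_cnvs = 4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("identical configs reproduce identical datasets and files", {
  d1 <- simulate_populations(small_cfg(seed = 5))
  d2 <- simulate_populations(small_cfg(seed = 5))
  expect_identical(d1$genotypes$geno, d2$genotypes$geno)
  expect_identical(d1$depths$depth, d2$depths$depth)
  expect_identical(d1$truth_cnvs, d2$truth_cnvs)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_dataset(d1, dir1); p2 <- write_dataset(d2, dir2)
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[k])), unname(tools::md5sum(p2[k])),
                     label = k)
  d3 <- simulate_populations(small_cfg(seed = 6))
  expect_false(identical(d1$genotypes$geno, d3$genotypes$geno))
})

test_that("complete selfing yields fully homozygous genotypes", {
  ds <- simulate_populations(small_cfg(selfing_rate = 1, seed = 2))
  expect_false(any(ds$genotypes$geno == 1L, na.rm = TRUE))
})

test_that("undifferentiated clusters give mean Weir-Cockerham F_ST near 0", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 30, n_chromosomes = 1,
                    chrom_length_bp = 5e6, n_snps = 600, n_targets = 60,
                    n_genes = 40, n_true_cnvs = 0, fst_between_clusters = 0,
                    seed = 3)
  ds <- simulate_populations(cfg)
  M <- fst_matrix(ds$genotypes, ds$popmap)
  expect_lt(abs(mean(M[upper.tri(M)])), 0.02)
})

test_that("fst parameter 0.3 realizes mean F_ST in the expected band", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 30, n_chromosomes = 1,
                    chrom_length_bp = 5e6, n_snps = 600, n_targets = 60,
                    n_genes = 40, n_true_cnvs = 0, fst_between_clusters = 0.3,
                    seed = 1)
  ds <- simulate_populations(cfg)
  M <- fst_matrix(ds$genotypes, ds$popmap)
  expect_gt(mean(M[upper.tri(M)]), 0.15)
  expect_lt(mean(M[upper.tri(M)]), 0.45)
})

test_that("realized F_ST increases monotonically with the parameter", {
  grid <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  reps <- 4
  par_v <- real_v <- c()
  for (fst in grid) for (r in seq_len(reps)) {
    cfg <- sim_config(n_clusters = 2, samples_per_cluster = 15, n_chromosomes = 1,
                      chrom_length_bp = 2e6, n_snps = 150, n_targets = 50,
                      n_genes = 20, n_true_cnvs = 0, fst_between_clusters = fst,
                      seed = round(1000 * fst) + r)
    ds <- simulate_populations(cfg)
    M <- fst_matrix(ds$genotypes, ds$popmap)
    par_v <- c(par_v, fst); real_v <- c(real_v, M[1, 2])
  }
  rho <- cor(par_v, real_v, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("truth CNV frequencies concentrate at low carrier frequency", {
  cfg <- sim_config(n_clusters = 4, samples_per_cluster = 15, n_chromosomes = 2,
                    chrom_length_bp = 1e7, n_snps = 200, n_targets = 1500,
                    n_genes = 80, n_true_cnvs = 60, seed = 9)
  ds <- simulate_populations(cfg)
  carr_n <- table(ds$truth_cnvs$carriers$cnv_id)
  freq <- as.numeric(carr_n) / nrow(ds$popmap)
  expect_gt(mean(freq < 0.1), mean(freq > 0.4))
  # every truth CNV spans at least cnv_min_targets contiguous targets
  expect_true(all(ds$truth_cnvs$cnvs$n_targets >= cfg$cnv_min_targets))
})

test_that("depth is exactly base x target effect with all noise off", {
  cfg <- small_cfg(n_true_cnvs = 0, n_batch_components = 0,
                   depth_noise_sd = 0, sample_effect_sd = 0, seed = 4)
  ds <- simulate_populations(cfg)
  d <- ds$depths$depth
  # every row identical, equal to base_depth * target effect
  for (i in 2:nrow(d)) expect_equal(unname(d[i, ]), unname(d[1, ]))
  expect_equal(mean(d[1, ]), cfg$base_depth, tolerance = 0.2)
})

test_that("a homozygous deletion zeroes the carrier's spanned targets", {
  cfg <- small_cfg(n_true_cnvs = 0, n_batch_components = 0,
                   depth_noise_sd = 0, sample_effect_sd = 0, seed = 4)
  ds <- simulate_populations(cfg)
  truth <- list(
    cnvs = data.frame(cnv_id = "cnv_001",
                      chrom = ds$depths$targets$chrom[10],
                      start = ds$depths$targets$start[10],
                      end = ds$depths$targets$end[14],
                      state = "DEL", target_first = 10L, target_last = 14L,
                      n_targets = 5L),
    carriers = data.frame(cnv_id = "cnv_001", sample = "S001", ratio = 0))
  dm <- simulate_read_depth(truth, ds$depths$targets, cfg,
                            sample_ids = ds$popmap$sample)
  expect_equal(unname(dm$depth[1, 10:14]), rep(0, 5))
  expect_gt(min(dm$depth[2, 10:14]), 1)
})

test_that("misaligned truth CNVs are rejected", {
  cfg <- small_cfg(seed = 4)
  ds <- simulate_populations(cfg)
  truth <- list(
    cnvs = data.frame(cnv_id = "x", chrom = ds$depths$targets$chrom[1],
                      start = ds$depths$targets$start[1] + 7L,
                      end = ds$depths$targets$end[3],
                      state = "DEL", target_first = 1L, target_last = 3L,
                      n_targets = 3L),
    carriers = data.frame(cnv_id = "x", sample = "S001", ratio = 0))
  expect_error(simulate_read_depth(truth, ds$depths$targets, cfg,
                                   ds$popmap$sample), "aligned")
})

test_that("two batch components dominate log-depth variance", {
  cfg <- sim_config(n_clusters = 3, samples_per_cluster = 10, n_chromosomes = 1,
                    chrom_length_bp = 5e6, n_snps = 100, n_targets = 800,
                    n_genes = 40, n_true_cnvs = 0, n_batch_components = 2,
                    seed = 7)
  ds <- simulate_populations(cfg)
  L <- scale(log(ds$depths$depth), scale = FALSE)
  ev <- svd(L)$d^2
  expect_gt(sum(ev[1:2]) / sum(ev), 0.5)
})

test_that("configs with too few SNPs per chromosome are rejected", {
  expect_error(simulate_populations(small_cfg(n_snps = 40, seed = 1)),
               ">= 50 per chromosome")
})

test_that("write_dataset refuses to overwrite and round-trips", {
  ds <- simulate_populations(small_cfg(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_error(write_dataset(ds, dir), "force")
  back <- read_vcf(paths[["vcf"]])
  expect_identical(back$geno, ds$genotypes$geno)
  dm <- read_depth_tsv(paths[["depth"]])
  expect_equal(dm$depth, ds$depths$depth, tolerance = 1e-9)
  bed <- read_bed(paths[["truth_cnvs"]], extra_cols = c("name", "state", "n_carriers"))
  expect_equal(nrow(bed), nrow(ds$truth_cnvs$cnvs))
  ann <- read_gene_annotation(paths[["genes"]], paths[["categories"]])
  expect_equal(sort(ann$genes$gene_id), sort(ds$annotation$genes$gene_id))
})

test_that("every sample appears exactly once in the popmap", {
  ds <- simulate_populations(small_cfg(seed = 12))
  expect_equal(anyDuplicated(ds$popmap$sample), 0L)
  expect_equal(nrow(ds$popmap), n_samples(ds$genotypes))
  expect_false(is.unsorted(ds$genotypes$sites$pos, strictly = TRUE))
})
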