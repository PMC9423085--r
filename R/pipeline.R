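# Pipeline orchestration: simulate -> target filter -> normalize -> CNV ->
# SNP filter -> diversity -> differentiation -> selection -> enrichment,
# from one resolved config with a JSON run manifest.

#' Pipeline run configuration
#'
#' Collects every stage parameter with the analysis defaults: SNP filter
#' quality 30 / depth 3x / missingness 0.10 / MAC 5; target size 100 bp
#' and depth window \[3x, 3000x\]; F_ST windows 100 kb step 50 kb;
#' Tajima's D windows 100 kb; H12 windows of 50 SNPs stepping 5; top 5
#' peaks longer than 150 kb; outlier alpha 0.01 with second-pass MAC 10
#' and 2 kb thinning; CNV-gene frequency threshold 0.20; 10,000
#' Monte-Carlo simulations. One global seed drives every stage through
#' derived sub-stream seeds.
#'
#' @param sim a [sim_config()] describing the synthetic input (or `NULL`
#'   when reading files via `input_dir`).
#' @param input_dir directory of dataset files (as written by
#'   [write_dataset()]) used when `sim` is `NULL`.
#' @param out_dir output directory for stage outputs and the manifest.
#' @param stages character vector of stages to run, in dependency order.
#' @param min_quality,min_mean_depth,max_missingness,min_allele_count
#'   first-pass SNP filter thresholds.
#' @param target_min_size,target_min_depth,target_max_depth exome-target
#'   filter thresholds.
#' @param n_components depth-normalization components to remove
#'   (`"auto"` or an integer; see [normalize_depth()]).
#' @param fst_window,fst_step F_ST sliding-window geometry (bp).
#' @param tajima_window Tajima's D window (bp, nonoverlapping).
#' @param h12_window,h12_step H12 window geometry (SNP counts).
#' @param top_peaks,min_peak_len peak-finder settings.
#' @param alpha outlier significance threshold (adjusted p).
#' @param outlier_mac,outlier_thin_bp second-pass filter for outlier scans.
#' @param n_pcs principal components for the outlier scan.
#' @param min_cluster_freq CNV-gene classification frequency threshold.
#' @param n_simulations Monte-Carlo simulations for enrichment tests.
#' @param external_outliers optional character vector of gene ids from an
#'   externally run outlier method, used as a third consensus input.
#' @param seed global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       out_dir = tempfile("lenspop_run_"),
                       stages = c("simulate", "cnv", "filter", "diversity",
                                  "differentiation", "selection", "enrichment"),
                       min_quality = 30, min_mean_depth = 3,
                       max_missingness = 0.10, min_allele_count = 5,
                       target_min_size = 100, target_min_depth = 3,
                       target_max_depth = 3000, n_components = "auto",
                       fst_window = 100000, fst_step = 50000,
                       tajima_window = 100000,
                       h12_window = 50L, h12_step = 5L,
                       top_peaks = 5L, min_peak_len = 150000,
                       alpha = 0.01, outlier_mac = 10, outlier_thin_bp = 2000,
                       n_pcs = 5L, min_cluster_freq = 0.20,
                       n_simulations = 10000L,
                       external_outliers = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `sim:` block maps to
#' [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  y$sim <- NULL
  do.call(run_config, c(list(sim = sim), y))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' outputs as TSV/BED under `config$out_dir`, and records a JSON manifest
#' with the resolved configuration and the MD5 checksum of every output
#' file. Reruns with an identical config reproduce identical checksums.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage's in-memory results plus
#'   `manifest` (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  st <- config$stages
  log_stage <- function(name, ...) message(sprintf("[lenspop:%s] %s", name,
                                                   sprintf(...)))
  # --- inputs ---------------------------------------------------------
  if ("simulate" %in% st) {
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, 1L)
    ds <- simulate_populations(sim_cfg)
    write_dataset(ds, file.path(config$out_dir, "dataset"), force = TRUE)
    log_stage("simulate", "%d samples, %d SNPs, %d truth CNVs",
              n_samples(ds$genotypes), n_sites(ds$genotypes),
              nrow(ds$truth_cnvs$cnvs))
  } else {
    if (is.null(config$input_dir)) stopf("no simulate stage and no input_dir")
    d <- config$input_dir
    ds <- list(
      genotypes = read_vcf(file.path(d, "snps.vcf")),
      depths = read_depth_tsv(file.path(d, "depth.tsv")),
      popmap = read_popmap(file.path(d, "popmap.tsv")),
      annotation = read_gene_annotation(file.path(d, "genes.bed"),
                                        file.path(d, "categories.tsv")))
  }
  res$dataset <- ds
  popmap <- ds$popmap
  genes <- ds$annotation$genes
  # --- CNV discovery (before the SNP filter: its regions feed the
  #     CNV-exclusion rule) ------------------------------------------
  if ("cnv" %in% st) {
    dm <- filter_targets(ds$depths, config$target_min_size,
                         config$target_min_depth, config$target_max_depth)
    ndm <- normalize_depth(dm, n_components = config$n_components)
    calls <- call_cnvs_hmm(ndm)
    catalog <- cnv_regions(calls)
    log_stage("cnv", "%d targets kept, %d PCs removed, %d calls, %d regions",
              nrow(dm$targets), ndm$n_components_removed, nrow(calls),
              nrow(catalog$regions))
    write.table(calls, file.path(config$out_dir, "cnv_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(catalog$regions, file.path(config$out_dir, "cnv_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$cnv <- list(ndm = ndm, calls = calls, catalog = catalog,
                    frequencies = cnv_frequencies(catalog, popmap),
                    burden = cnv_burden(calls, popmap))
  }
  cnv_regions_df <- if (!is.null(res$cnv)) res$cnv$catalog$regions else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  # --- SNP filtering --------------------------------------------------
  if ("filter" %in% st) {
    fp <- filter_params(min_quality = config$min_quality,
                        min_mean_depth = config$min_mean_depth,
                        max_missingness = config$max_missingness,
                        min_allele_count = config$min_allele_count,
                        exclude_regions = cnv_regions_df)
    gm <- filter_variants(ds$genotypes, fp)
    log_stage("filter", "%d -> %d SNPs", n_sites(ds$genotypes), n_sites(gm))
    write.table(attr(gm, "filter_report"),
                file.path(config$out_dir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$filtered <- gm
  } else gm <- ds$genotypes
  clusters <- sort(unique(popmap$cluster))
  # --- diversity ------------------------------------------------------
  if ("diversity" %in% st) {
    seg <- segregating_sites(gm, popmap)
    gmax <- 2L * min(table(popmap$cluster))
    rich <- rarefied_richness(gm, popmap, g = max(2L, gmax - 2L))
    sfs <- lapply(clusters, function(cl) {
      obs <- observed_sfs_snp(gm, popmap, cl)
      list(observed = obs,
           expected = expected_sfs_watterson(obs$n, round(sum(obs$counts))))
    })
    names(sfs) <- clusters
    res$diversity <- list(segregating_sites = seg, richness = rich, sfs = sfs)
    write.table(rich, file.path(config$out_dir, "rarefied_richness.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("diversity", "segregating sites: %s",
              paste(sprintf("%s=%d", clusters, seg), collapse = " "))
  }
  # --- differentiation ------------------------------------------------
  if ("differentiation" %in% st) {
    fstM <- fst_matrix(gm, popmap)
    vstRes <- if (!is.null(res$cnv) && nrow(cnv_regions_df) > 0)
      vst_matrix(res$cnv$ndm, res$cnv$catalog$regions, popmap) else NULL
    res$differentiation <- list(fst_matrix = fstM, vst = vstRes)
    write.table(fstM, file.path(config$out_dir, "fst_matrix.tsv"),
                sep = "\t", quote = FALSE)
    log_stage("differentiation", "mean pairwise FST %.3f",
              mean(fstM[upper.tri(fstM)]))
  }
  # --- selection ------------------------------------------------------
  if ("selection" %in% st) {
    taj <- lapply(clusters, function(cl)
      tajimas_d_windows(gm, popmap, cl, window = config$tajima_window))
    names(taj) <- clusters
    h12 <- suppressWarnings(
      h12_scan(gm, config$h12_window, config$h12_step))
    peaks <- find_peaks(h12, config$top_peaks, config$min_peak_len)
    sweep_genes <- regions_to_genes(
      data.frame(chrom = peaks$chrom, start = peaks$start - 1L,
                 end = peaks$end), genes)
    # second-pass filter before the outlier scan
    gm2 <- filter_variants(gm, filter_params(
      min_quality = 0, min_mean_depth = config$min_mean_depth,
      max_missingness = 1, min_allele_count = config$outlier_mac,
      exclude_regions = cnv_regions_df,
      min_distance_bp = config$outlier_thin_bp))
    outl <- pca_outlier_scan(gm2, n_pcs = min(config$n_pcs,
                                              n_samples(gm2) - 1L),
                             alpha = config$alpha)
    outlier_genes <- regions_to_genes(outl$snps[outl$snps$flagged,
                                                c("chrom", "pos")], genes)
    sets <- list(h12 = sweep_genes, pca_outlier = outlier_genes)
    if (!is.null(config$external_outliers))
      sets$external <- config$external_outliers
    consensus <- consensus_candidates(sets, min_methods = 2L)
    res$selection <- list(tajima = taj, h12 = h12, peaks = peaks,
                          outliers = outl, method_genes = sets,
                          consensus = as.character(consensus))
    write.table(h12, file.path(config$out_dir, "h12_track.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(peaks, file.path(config$out_dir, "h12_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(consensus),
               file.path(config$out_dir, "consensus_genes.txt"))
    log_stage("selection", "%d peaks, %d outlier SNPs, %d consensus genes",
              nrow(peaks), sum(outl$snps$flagged), length(consensus))
  }
  # --- enrichment -----------------------------------------------------
  if ("enrichment" %in% st && !is.null(res$cnv)) {
    aff <- genes_in_cnv_regions(res$cnv$catalog, genes, popmap,
                                config$min_cluster_freq)
    enr <- if (length(aff$global))
      category_enrichment(aff$global, genes, ds$annotation$categories,
                          n_simulations = config$n_simulations,
                          seed = derive_seed(config$seed, 6L)) else NULL
    resov <- if (length(aff$global) && any(genes$resistance))
      resistance_overlap(aff$global, genes,
                         n_simulations = config$n_simulations,
                         seed = derive_seed(config$seed, 8L)) else NULL
    res$enrichment <- list(affected = aff, category = enr, resistance = resov)
    if (!is.null(enr))
      write.table(enr$table, file.path(config$out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("enrichment", "%d affected genes, chi^2 p = %s",
              length(aff$global),
              if (is.null(enr)) "NA" else format(enr$p_value))
  }
  # --- manifest -------------------------------------------------------
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lenspop")),
    seed = config$seed,
    stages = st,
    config = config_to_list(config),
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               sub(paste0(config$out_dir, "/?"), "", files)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- if (!is.null(out$sim)) unclass(out$sim) else NULL
  if (!is.null(out$sim$sweep_positions))
    out$sim$sweep_positions <- as.list(out$sim$sweep_positions)
  out
}
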