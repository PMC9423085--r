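# Standard-format IO and the two SNP filtering passes.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parsing is delegated to \pkg{vcfR}. Genotypes are coded as the number of
#' non-reference alleles (0/1/2); any missing allele makes the call `NA`.
#' Multiallelic records are retained but flagged `biallelic = FALSE`
#' (non-reference alleles are pooled for their dosage code). Per-site mean
#' depth is taken from the per-sample FORMAT `DP` field when present,
#' otherwise from INFO `DP` divided by the sample count.
#'
#' @param path path to a VCF (optionally gzipped) with a GT FORMAT field.
#' @return A [genotype_matrix()]; sample order as in the VCF.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stopf("VCF '%s' contains no records", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(gt)
  codes <- gt_to_dosage(gt)          # sites x samples
  n <- length(sample_ids)
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (!is.null(dp) && !all(is.na(dp))) {
    mean_depth <- rowMeans(dp, na.rm = TRUE)
  } else {
    info <- paste0(";", fix$INFO)
    has_dp <- grepl(";DP=", info, fixed = TRUE)
    info_dp <- rep(NA_real_, length(info))
    info_dp[has_dp] <- suppressWarnings(as.numeric(
      sub(".*;DP=([0-9.eE+-]+).*", "\\1", info[has_dp])))
    mean_depth <- info_dp / n
  }
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mean_depth = mean_depth,
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(codes), sites, sample_ids)
}

# "0/1", "1|1", "./." ... -> dosage of non-ref alleles; NA on any ".".
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || length(al) == 0L) return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as a VCFv4.2 file
#'
#' Plain-text writer for round-tripping simulated datasets. Dosage codes
#' map to unphased GT (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.); per-site
#' mean depth is stored as INFO `DP` (total depth = mean x samples).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  n <- n_samples(gm)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lenspop",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Total depth across samples\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gm$sample_ids), collapse = "\t")
  )
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n, ncol = n_sites(gm))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_map[gm$geno[ok] + 1L]
  rec <- paste(
    s$chrom, s$pos, ".", s$ref, s$alt,
    sprintf("%.10g", s$qual), "PASS",
    sprintf("DP=%.15g", s$mean_depth * n),
    "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' SNP filter thresholds
#'
#' Defaults are the standard exome-capture panel filter: site quality >= 30,
#' mean depth >= 3x, missingness <= 0.10, minor allele count >= 5,
#' biallelic only, with optional exclusion regions (e.g. CNV regions) and
#' optional distance thinning.
#'
#' @param min_quality minimum site quality score.
#' @param min_mean_depth minimum per-site mean depth (x coverage).
#' @param max_missingness maximum per-site missing-call fraction.
#' @param min_allele_count minimum minor-allele count (over non-missing
#'   allele copies).
#' @param biallelic_only drop multiallelic records?
#' @param exclude_regions optional data.frame (`chrom`, `start`, `end`;
#'   0-based half-open) of regions whose SNPs are removed.
#' @param min_distance_bp optional thinning distance (see [thin_variants()]);
#'   `NULL` to skip.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_quality = 30, min_mean_depth = 3,
                          max_missingness = 0.10, min_allele_count = 5,
                          biallelic_only = TRUE, exclude_regions = NULL,
                          min_distance_bp = NULL) {
  assert_scalar_num(min_quality, "min_quality", min = 0)
  assert_scalar_num(min_mean_depth, "min_mean_depth", min = 0)
  assert_scalar_num(max_missingness, "max_missingness", min = 0, max = 1)
  assert_scalar_num(min_allele_count, "min_allele_count", min = 0)
  structure(list(min_quality = min_quality, min_mean_depth = min_mean_depth,
                 max_missingness = max_missingness,
                 min_allele_count = min_allele_count,
                 biallelic_only = biallelic_only,
                 exclude_regions = exclude_regions,
                 min_distance_bp = min_distance_bp),
            class = "filter_params")
}

#' Filter SNP sites
#'
#' A site survives iff quality >= `min_quality`, mean depth >=
#' `min_mean_depth`, missingness <= `max_missingness`, it is biallelic
#' (when `biallelic_only`), its minor-allele count is >= `min_allele_count`,
#' and it does not fall inside any exclusion region. Site order is
#' preserved. The per-rule removal report attributes each removed site to
#' the *first* rule it fails, in the order quality, depth, missingness,
#' biallelic, MAC, region; counts therefore sum to input - output sites.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [filter_params()].
#' @return A filtered `genotype_matrix` with the removal report attached as
#'   `attr(, "filter_report")` (data.frame `rule`, `n_removed`).
#' @export
filter_variants <- function(gm, params) {
  stopifnot(inherits(params, "filter_params"))
  s <- gm$sites
  ac <- allele_counts(gm)
  fails <- list(
    quality = !(s$qual >= params$min_quality) | is.na(s$qual),
    depth = !(s$mean_depth >= params$min_mean_depth) | is.na(s$mean_depth),
    missingness = site_missingness(gm) > params$max_missingness,
    biallelic = if (params$biallelic_only) !s$biallelic else rep(FALSE, nrow(s)),
    mac = ac$minor < params$min_allele_count,
    region = if (!is.null(params$exclude_regions))
      points_in_regions(s$chrom, s$pos, params$exclude_regions)
    else rep(FALSE, nrow(s))
  )
  removed_by <- rep(NA_character_, nrow(s))
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  keep <- is.na(removed_by)
  report <- data.frame(
    rule = names(fails),
    n_removed = vapply(names(fails), function(r) sum(removed_by == r, na.rm = TRUE),
                       integer(1)),
    row.names = NULL
  )
  if (!any(keep)) warnf("all %d sites removed by filtering", nrow(s))
  out <- subset_gm(gm, sites = keep)
  if (!is.null(params$min_distance_bp) && params$min_distance_bp > 0)
    out <- thin_variants(out, params$min_distance_bp)
  attr(out, "filter_report") <- report
  out
}

#' Thin SNPs by a minimum inter-site distance
#'
#' Greedy left-to-right scan per chromosome: the first site on each
#' chromosome is always kept; a later site is kept iff its position is at
#' least `min_distance_bp` beyond the last kept position.
#'
#' @param gm a [genotype_matrix()] with sites sorted by position.
#' @param min_distance_bp minimum distance in bp (0 = identity).
#' @return A thinned `genotype_matrix`.
#' @export
thin_variants <- function(gm, min_distance_bp) {
  assert_scalar_num(min_distance_bp, "min_distance_bp", min = 0)
  keep <- logical(n_sites(gm))
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (gm$sites$pos[i] >= last + min_distance_bp) {
        keep[i] <- TRUE
        last <- gm$sites$pos[i]
      }
    }
  }
  subset_gm(gm, sites = keep)
}

#' Read a population map (sample -> cluster)
#'
#' @param path TSV with columns `sample`, `cluster` (header required).
#' @return data.frame with character columns `sample`, `cluster`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("sample", "cluster") %in% names(pm)))
    stopf("popmap must have columns 'sample' and 'cluster'")
  if (anyDuplicated(pm$sample)) stopf("duplicate samples in popmap")
  pm
}

#' Read a per-target read-depth matrix
#'
#' @param path TSV whose first three columns are `chrom`, `start`, `end`
#'   (0-based half-open target intervals) followed by one numeric column
#'   per sample.
#' @return A [depth_matrix()].
#' @export
read_depth_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  targets <- df[, c("chrom", "start", "end")]
  depth <- t(as.matrix(df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]))
  depth_matrix(targets, rownames(depth), depth)
}

#' Write a depth matrix as TSV (targets as rows, samples as columns)
#' @param dm a [depth_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(dm, path) {
  df <- cbind(dm$targets, as.data.frame(t(dm$depth), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of intervals
#'
#' @param path BED path (no header; 0-based half-open).
#' @param extra_cols optional names for columns beyond chrom/start/end.
#' @return data.frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols))
    names(df)[seq(4L, length.out = min(length(extra_cols), ncol(df) - 3L))] <-
      extra_cols[seq_len(min(length(extra_cols), ncol(df) - 3L))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read gene annotation (BED intervals + category/resistance table)
#'
#' @param bed_path BED4 of gene intervals (4th column = gene id).
#' @param categories_path TSV with columns `gene_id`, `category`,
#'   `resistance` (0/1); one row per gene-category pair.
#' @return A list with `genes` (data.frame gene_id/chrom/start/end/resistance)
#'   and `categories` (data.frame gene_id/category).
#' @export
read_gene_annotation <- function(bed_path, categories_path) {
  genes <- read_bed(bed_path, extra_cols = "gene_id")
  cats <- read.table(categories_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  res <- tapply(cats$resistance, cats$gene_id, function(x) any(x > 0))
  genes$resistance <- as.logical(res[genes$gene_id])
  genes$resistance[is.na(genes$resistance)] <- FALSE
  list(genes = genes[, c("gene_id", "chrom", "start", "end", "resistance")],
       categories = cats[cats$category != "" & !is.na(cats$category),
                         c("gene_id", "category")])
}
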