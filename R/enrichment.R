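# Gene-CNV intersection, per-cluster classification at a frequency
# threshold, and functional-category enrichment via Monte-Carlo
# chi-squared tests; resistance-gene overlap test.

#' Genes affected by CNV regions, per cluster and globally
#'
#' A gene is "affected" in a cluster iff some CNV region whose combined
#' carrier frequency in that cluster is strictly greater than
#' `min_cluster_freq` overlaps the gene (half-open overlap). The
#' unthresholded global set collects genes overlapped by any region.
#'
#' @param catalog a [cnv_regions()] catalog.
#' @param annotation data.frame of gene intervals (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param popmap data.frame `sample`, `cluster`.
#' @param min_cluster_freq frequency threshold (default 0.20, strict
#'   inequality).
#' @return list with `per_cluster` (named list of gene-id vectors) and
#'   `global` (gene-id vector).
#' @export
genes_in_cnv_regions <- function(catalog, annotation, popmap,
                                 min_cluster_freq = 0.20) {
  freqs <- cnv_frequencies(catalog, popmap)
  regions <- catalog$regions
  ov <- overlap_pairs0(regions[, c("chrom", "start", "end")], annotation)
  genes_of_region <- split(annotation$gene_id[ov$s_idx],
                           regions$region_id[ov$q_idx])
  clusters <- sort(unique(popmap$cluster))
  per_cluster <- lapply(clusters, function(cl) {
    rid <- freqs$region_id[freqs$cluster == cl & freqs$freq_any > min_cluster_freq]
    sort(unique(unlist(genes_of_region[as.character(rid)])))
  })
  names(per_cluster) <- clusters
  list(per_cluster = per_cluster,
       global = sort(unique(unlist(genes_of_region))))
}

# gene x category incidence matrix over the closed category vocabulary;
# genes without any label get "Not assigned".
category_incidence <- function(gene_ids, categories) {
  cats <- categories[categories$gene_id %in% gene_ids, , drop = FALSE]
  labelled <- unique(cats$gene_id)
  if (length(setdiff(gene_ids, labelled)))
    cats <- rbind(cats, data.frame(gene_id = setdiff(gene_ids, labelled),
                                   category = "Not assigned"))
  vocab <- sort(unique(cats$category))
  M <- matrix(0L, nrow = length(gene_ids), ncol = length(vocab),
              dimnames = list(gene_ids, vocab))
  M[cbind(match(cats$gene_id, gene_ids), match(cats$category, vocab))] <- 1L
  M
}

#' Functional-category enrichment with a Monte-Carlo chi-squared test
#'
#' Tests whether a gene set is randomly distributed over functional
#' categories. Observed per-category counts (a multi-label gene
#' contributes one count per label) are compared with expectations
#' proportional to genome-wide category frequencies via the chi-squared
#' statistic; the null distribution is built by drawing `|gene_set|`
#' genes uniformly without replacement from the annotation `n_simulations`
#' times, carrying their labels. p = (1 + #\{null >= observed\}) /
#' (n_simulations + 1), one-sided. Per-category standardized residuals
#' (obs - exp) / sqrt(exp) mark over/under-represented categories.
#'
#' @param gene_set non-empty character vector of gene ids.
#' @param annotation data.frame of all genes (`gene_id`, ...).
#' @param categories data.frame `gene_id`, `category` (one row per label).
#' @param n_simulations Monte-Carlo draws (default 10000; must be >= 1).
#' @param seed integer RNG seed for the draws.
#' @return list of class `enrichment_result`: `table` (per-category
#'   `category`, `observed`, `expected`, `residual`, `direction`),
#'   `chisq`, `p_value`, `n_simulations`, `seed`.
#' @export
category_enrichment <- function(gene_set, annotation, categories,
                                n_simulations = 10000L, seed = 1L) {
  if (!length(gene_set)) stopf("gene_set is empty")
  if (n_simulations < 1L) stopf("n_simulations must be >= 1")
  gene_set <- unique(gene_set)
  all_genes <- annotation$gene_id
  M <- category_incidence(all_genes, categories)
  in_set <- match(gene_set, all_genes)
  if (anyNA(in_set)) stopf("gene_set contains ids absent from the annotation")
  bg_counts <- colSums(M)
  bg_prop <- bg_counts / sum(bg_counts)
  chisq_of <- function(idx) {
    obs <- colSums(M[idx, , drop = FALSE])
    expd <- bg_prop * sum(obs)
    ok <- expd > 0
    sum((obs[ok] - expd[ok])^2 / expd[ok])
  }
  obs_counts <- colSums(M[in_set, , drop = FALSE])
  obs_exp <- bg_prop * sum(obs_counts)
  stat <- chisq_of(in_set)
  set.seed(seed)
  null_ge <- 0L
  ngen <- length(all_genes); k <- length(in_set)
  for (b in seq_len(n_simulations))
    if (chisq_of(sample.int(ngen, k)) >= stat) null_ge <- null_ge + 1L
  resid <- ifelse(obs_exp > 0, (obs_counts - obs_exp) / sqrt(obs_exp), NA_real_)
  structure(list(
    table = data.frame(category = colnames(M), observed = as.numeric(obs_counts),
                       expected = obs_exp, residual = resid,
                       direction = ifelse(obs_counts > obs_exp, "over", "under"),
                       row.names = NULL, stringsAsFactors = FALSE),
    chisq = stat,
    p_value = (1 + null_ge) / (n_simulations + 1),
    n_simulations = n_simulations, seed = seed),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: chi^2 = %.2f, Monte-Carlo p = %.4g (%d sims)\n",
              x$chisq, x$p_value, x$n_simulations))
  top <- x$table[order(-x$table$residual), ]
  print(head(top, 5))
  invisible(x)
}

#' Resistance-gene overlap with CNV-affected genes
#'
#' One-sided Monte-Carlo test of whether the affected gene set contains
#' more disease-resistance genes than expected under uniform gene
#' resampling.
#'
#' @param affected_genes character vector of gene ids (may be empty).
#' @param annotation data.frame with `gene_id` and logical `resistance`.
#' @param n_simulations Monte-Carlo draws (default 10000).
#' @param seed integer RNG seed.
#' @return list: `observed` (count of affected resistance genes),
#'   `expected` (mean under the null), `p_value`, `n_resistance`,
#'   `n_affected`.
#' @export
resistance_overlap <- function(affected_genes, annotation,
                               n_simulations = 10000L, seed = 1L) {
  res <- annotation$gene_id[annotation$resistance]
  if (!length(res)) stopf("annotation contains no resistance genes")
  affected_genes <- unique(affected_genes)
  obs <- length(intersect(affected_genes, res))
  k <- length(affected_genes)
  set.seed(seed)
  is_res <- annotation$resistance
  null_counts <- if (k == 0L) rep(0L, n_simulations) else
    vapply(seq_len(n_simulations), function(b)
      sum(is_res[sample.int(length(is_res), k)]), integer(1))
  list(observed = obs, expected = mean(null_counts),
       p_value = (1 + sum(null_counts >= obs)) / (n_simulations + 1),
       n_resistance = length(res), n_affected = k)
}
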