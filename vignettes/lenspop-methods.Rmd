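---
title: "Methods: joint SNP and CNV population genomics for selfing crop panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint SNP and CNV population genomics for selfing crop panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenspop)
```

`lenspop` implements a complete population-genomics workflow for a
diversity panel of a highly selfing diploid crop genotyped by exome
capture, treating single-nucleotide polymorphisms (SNPs) and copy-number
variants (CNVs) as two complementary views of the same panel. This
vignette explains the statistical models behind each stage, the
parameters that matter (with defaults and the reasoning behind them),
what the synthetic-data generator does and does not emulate, and the
numerical choices a maintainer should know about.

## The analysis at a glance

1. **CNV discovery** from a samples × exome-targets read-depth matrix:
   target QC, PCA normalization, and a three-state hidden Markov model
   (deletion / diploid / duplication) decoded per sample.
2. **SNP filtering** from a multi-sample VCF: site quality ≥ 30, mean
   depth ≥ 3×, missingness ≤ 0.10, minor-allele count (MAC) ≥ 5,
   biallelic only, and removal of SNPs inside discovered CNV regions.
3. **Diversity** per cluster: segregating sites, rarefied allelic and
   private allelic richness, observed site-frequency spectra (SFS) for
   SNPs and CNV carriers, and the Watterson-expected SFS.
4. **Differentiation**: per-site and windowed Weir–Cockerham
   F~ST~ (100 kb windows, 50 kb step) from SNPs; V~ST~ from normalized
   read depth for CNV regions.
5. **Selection**: windowed Tajima's D (100 kb, nonoverlapping), an H12
   haplotype-homozygosity scan (50-SNP windows, 5-SNP step) with peak
   finding (top 5 peaks per chromosome, span > 150 kb), a PCA-based
   outlier scan (α = 0.01 after Benjamini–Hochberg), and a gene-level
   consensus requiring at least two methods.
6. **Enrichment**: genes overlapped by CNV regions at cluster frequency
   strictly above 0.20, functional-category enrichment by Monte-Carlo
   χ² (10,000 simulations), and a resistance-gene overlap test.

Cluster assignments are an input (a `sample → cluster` population map);
the package does not fit an ancestry model.

## CNV discovery from exome read depth

### Depth normalization

Exome read depth is dominated by systematic structure — capture
efficiency per target, sample-level depth, and batch effects — on top of
which CNVs are localized multiplicative shifts (a heterozygous deletion
halves depth; a homozygous deletion removes it). The normalization
follows the standard recipe of depth-based exome CNV callers: center
each target, estimate principal components across samples, subtract the
projections on the leading components, and z-score the residual per
sample. `n_components = "auto"` removes every component whose variance
share exceeds 0.7/n~samples~, the usual relative-threshold convention.

On panels with a few thousand targets, rare-CNV outliers are **not** a
negligible share of total variance, and the textbook recipe fails in
ways that matter:

* **Column centering.** A plain mean is dragged by carriers at the CNV's
  own targets; a median makes discrete batch structure rank-2 instead of
  rank-1 (two unequal batches no longer cancel). We center each target
  by its 20%-trimmed mean: robust to a rare CNV's carriers, smooth
  enough to keep low-rank structure low-rank.
* **Component and coefficient estimation.** Homozygous deletions sit at
  around −10 z; if such outliers enter either the eigenvectors or the
  projection coefficients, the subtraction *imprints* an inverted copy
  of the carrier pattern on every non-carrier, which the HMM then calls.
  Both the SVD and the subtracted structure are therefore estimated from
  a copy of the matrix winsorized at 2 column-MADs; the winsorization
  limit scales with each column's own spread, so genuine batch tails are
  not clipped.
* **Row scale.** The final z-score uses the MAD-consistent robust SD per
  sample, so a sample's own CNVs do not inflate its scale and shrink all
  its z-scores. For clean Gaussian data every one of these choices
  reduces to the classical mean/SD convention.

A limitation worth knowing: when the CNV catalog itself is large and
population-structured, the aggregate carrier-burden direction of a
strongly drifted cluster can exceed the "auto" variance threshold and be
removed — subtracting exactly the between-population signal that
V~ST~ measures. When the systematic design is known (k batch components
plus a sample effect), pass a fixed `n_components`; the differentiation
tests in this package do so.

### The HMM

Per sample and chromosome, the ordered target z-scores are decoded with
a three-state HMM: Gaussian emissions at −3 (deletion), 0 (diploid), +3
(duplication) z with unit SD; a per-target prior of 10^−4^ of entering a
CNV state; a geometric dwell with mean 6 targets. The paper trail for
these values is the convention of depth-based exome callers; all are
exposed in `hmm_params()`. Viterbi decoding gives the state path;
consecutive non-diploid targets merge into calls whose quality is the
mean forward–backward posterior over the spanned targets.

Two standard QC screens are applied to merged calls by default: quality
≥ 0.9 and span ≥ 2 targets. Heavy-tailed multiplicative depth noise
produces occasional single-target z excursions beyond ±4 whose posterior
is nevertheless mediocre; the screens remove them while leaving
multi-target calls (posterior ≈ 1) untouched. Both screens can be
disabled (`min_quality = 0, min_targets = 1`), which restores the exact
Viterbi segmentation — the mode used when verifying that call spans
conserve the decoded state assignments.

Calls are merged across samples into CNV regions by union overlap;
a region may carry deletion carriers in some accessions and duplication
carriers in others, as observed in real panels.

## SNP statistics

**Weir–Cockerham F~ST~** uses the diploid variance-components estimator
for two populations with unequal sample sizes (components *a*, *b*, *c*;
θ̂ = a/(a+b+c)); multi-locus and windowed values combine as the ratio of
sums Σa/Σ(a+b+c), the standard multi-locus combination, with a
mean-of-ratios option for strict replication of per-site-averaging
tools. The estimator is validated in the tests against an independent
allele-indicator ANOVA implementation to 10^−12^.

**Tajima's D** per 100 kb nonoverlapping window uses π from per-site
allele counts, θ~W~ = S/a~1~, and the standard 1989 variance constants;
windows with fewer than 3 segregating sites are flagged missing. With
missing genotypes the constants use the rounded mean non-missing
chromosome count over the window's segregating sites.

**V~ST~** for a CNV region is (V~T~ − V~S~)/V~T~, where each sample's
value is its mean normalized depth over the region's targets, V~T~ is
the pooled two-cluster sample variance (n−1 denominator) and V~S~ the
sample-size-weighted mean of within-cluster variances. The n−1
convention matters near zero: the two-point case {0,2} vs {0,2} gives
exactly −0.5. V~ST~ is invariant under affine maps of the depth values.

**Rarefaction.** Allelic richness at standardized subsample size *g*
gene copies sums, over alleles with *N~a~* of *N* copies,
1 − C(N−N~a~, g)/C(N, g), averaged over loci; private richness
multiplies each allele's presence probability in the focal cluster by
the probability that size-*g* subsamples of every other cluster contain
no copy. Exactness is verified against exhaustive subset enumeration for
loci with up to 8 gene copies.

**Spectra.** The SNP SFS treats the alternate allele as derived
(reference-as-ancestral; a folded option exists). Sites with missing
data are projected onto a common chromosome count by the hypergeometric
down-projection, preserving segregating sites. The CNV spectrum counts
carrier samples per region — depth calls do not resolve allele dosage —
so its n is the cluster sample count. The neutral expectation is
θ~W~/i per derived-count class i with θ~W~ = S/Σ1/i, which totals S
exactly.

## Selection scans

**H12** reduces each sample to a pseudo-haplotype (homozygous calls map
to one allele; heterozygous calls become missing — appropriate at a
selfing rate of 0.95, where heterozygotes are rare). Within each 50-SNP
window, haplotypes missing more than 20% of sites are dropped and
residual missing entries take the window's major allele;
H12 = (p₁+p₂)² + Σ~i≥3~ p~i~², pooling the top two haplotype
frequencies so both hard and soft sweeps score highly. Peaks are
contiguous above-threshold runs (default threshold: track median +
2×MAD — a robust, scale-free choice the user can override), discarded
if their span does not exceed 150 kb (the LD-decay scale of a selfing
crop; shorter runs are likely noise), ranked by maximum H12 with ties
broken leftmost, and capped at 5 per chromosome.

**PCA outlier scan.** SNPs are standardized and mean-imputed; per SNP
the vector of regression z-statistics on the top `n_pcs` principal
component scores is summarized as a Mahalanobis distance under a robust
covariance estimate (so that the very outliers being hunted cannot mask
themselves), rescaled by the genomic-inflation factor (median distance
over the χ² median), and converted to χ²~n_pcs~ p-values with
Benjamini–Hochberg adjustment at α = 0.01. Two practical notes. First,
the second-pass variant filter (MAC ≥ 10, 2 kb thinning, CNV-region
exclusion) belongs *before* this scan: rare variants have unstable
per-SNP residual variances and inflate the null tail roughly twofold.
Second, a SNP lying on a swept haplotype can be almost perfectly
collinear with a principal component, making its regression residual
collapse to zero; the residual SD is floored so such SNPs emerge as the
extreme outliers they are rather than degenerate cases.

**Consensus.** Gene-level results from the sweep scan (genes overlapping
peaks), the outlier scan (genes containing flagged SNPs), and optionally
an externally produced outlier list are intersected; genes seen by at
least two methods are the reported candidates.

## Enrichment

Genes overlapped by a CNV region whose carrier frequency in a cluster is
*strictly greater* than 0.20 are that cluster's affected set; the global
affected set is unthresholded. Category enrichment compares observed
per-category counts (a multi-label gene contributes one count per label)
with expectations proportional to genome-wide category frequencies via
the χ² statistic; the null resamples equally sized gene sets uniformly
without replacement, carrying their labels, and the one-sided
Monte-Carlo p-value is (1 + #{null ≥ observed})/(n~sim~ + 1) — bounded
below by 1/(n~sim~+1), never zero. Per-category standardized residuals
flag over/under-representation. The resistance-gene overlap test uses
the same null for the count of affected resistance genes.

## The synthetic-data generator

The generator produces a complete panel — genotypes, read depths, truth
CNVs, gene annotation with functional categories and resistance flags,
and a population map — whose statistical structure matches what the
analysis assumes, so that every stage is testable end to end without any
external data. Defaults describe a desk-scale selfing diversity panel:
8 clusters × 12 accessions, 7 chromosomes of 10 Mb, 7,000 exome SNPs
(80% placed within genes ± 1 kb, as exome capture concentrates them),
3,500 targets, 1,050 genes, selfing rate 0.95, between-cluster F~ST~
0.2, 22× coverage, and 60 CNVs.

**Genotypes.** Ancestral derived-allele counts are drawn with neutral
1/i weights. With `fst_between_clusters = 0` the count is split exactly
across clusters (multivariate hypergeometric), so the panel-wide SFS is
exactly multinomial around the Watterson expectation — the χ²
goodness-of-fit calibration the tests rely on. With differentiation,
each cluster receives its own Balding–Nichols drift coefficient
(log-normally spread around the F~ST~ parameter and mean-normalized):
real panels are differentiated hierarchically, and without per-cluster
drift all pairs would be equally differentiated in expectation and the
F~ST~/V~ST~ congruence the analysis reports would have nothing to
detect. Within a cluster, derived copies are placed under
selfing-equilibrium autozygosity (F = s/(2−s)), keeping the allele
count exact while genotype homozygosity matches the selfing rate; at
`selfing_rate = 1` every genotype is homozygous.

**Sweeps.** Each sweep fixes one haplotype — homozygous derived across
the span (default 400 kb) — in a fraction (default 0.95) of one
designated cluster, the classic hard-sweep footprint in a selfer.

**CNVs.** Implanted on contiguous target runs (≥ `cnv_min_targets`),
with carrier frequencies drawn Beta(0.5, 6) capped at 0.1 and realized
carrier counts capped at 15% of the panel: the rare-variant regime that
purifying selection imposes on real CNVs, that the low-frequency-excess
observation reflects, and that the normalization's trimmed centering
assumes. Cluster-level frequencies disperse with the same per-cluster
drift as SNPs. Carriers are predominantly homozygous (90% carry two
altered copies), as expected at a selfing rate of 0.95. The
`cnv_z_shift` parameter is a *floor* on the post-normalization |z| of a
single-copy change: the default depth-noise SD is 0.3/`cnv_z_shift`,
which absorbs worst-case attenuation from carrier-frequency centering
and below-average capture efficiency.

**Depth.** Multiplicative: base depth × gamma capture efficiency
(shape 50) × log-normal sample effect (SD 0.07) × batch structure ×
log-normal noise × the carrier's copy ratio (deletion 0 or 0.5,
duplication 2 or 1.5). Batch components assign each sample to one of two
discrete batches (±1 × SD 0.1, Gaussian target loadings) — the realistic
model of sequencing batches, and one that keeps the multiplicative
structure exactly low-rank on the raw-depth scale so PCA can remove it
fully; with Gaussian sample loadings the exponential of a rank-2
log-structure has a rank-4 interaction whose weak components fall below
any removal threshold and surface as spurious calls. Two batch
components explain more than half of log-depth variance under the
defaults.

**What the generator does not emulate** — and hence what green tests do
not establish about real data: linkage disequilibrium within clusters
beyond sweeps (sites are exchangeable), gene flow and admixture
gradients between clusters, reference-bias and mapping artifacts in
depth, GC-content effects, breakpoints off target boundaries, and
dosage-variable CNV alleles. Results on real panels additionally depend
on upstream read processing, which is outside this package's scope (the
pipeline starts from a VCF and a depth matrix).

## Problem sizes and reproducibility

The test-suite and acceptance-script problem sizes (panels of 50–125
samples, 800–7,000 SNPs, up to 6,000 targets, 5-seed replication) were
chosen as the smallest sizes at which each statistical property is
stably observable — e.g. CNV recovery is measured at 50 samples × 2,000
targets with 30 implanted CNVs, and F~ST~/V~ST~ congruence needs a
250-region catalog before pair rankings rise above sampling noise.
Every random draw descends from a single integer seed through fixed
sub-stream derivation (`derive_seed()`), so identical configurations
reproduce byte-identical datasets, and the pipeline manifest records
MD5 checksums of every output to make reruns verifiable.

## Known limitations

* Region boundaries are target-resolution; breakpoints inside targets
  are not refined.
* The CNV caller genotypes carrier status, not allele dosage; all
  carrier-frequency statistics (spectra, V~ST~ inputs, privacy) inherit
  that resolution.
* The "auto" component threshold can remove population-structured CNV
  signal from large catalogs (see above); inspect removed components
  against known covariates, or fix `n_components`.
* The Monte-Carlo χ² null resamples genes uniformly; clustered gene
  families violate exchangeability and can make the test anticonservative
  for categories organized in tandem arrays.
* Tajima's D constants assume a single n per window; heavy,
  heterogeneous missingness makes the rounded-mean-n approximation
  coarse.
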