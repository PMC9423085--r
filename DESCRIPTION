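Package: lenspop
Title: SNP and Copy-Number Population Genomics for Selfing Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for joint SNP and copy-number-variant (CNV)
    population genomics in highly selfing crop diversity panels. Implements
    VCF-based SNP filtering, read-depth CNV discovery from exome capture
    targets (PCA normalization followed by a three-state hidden Markov
    model), per-cluster diversity statistics (segregating sites, rarefied
    allelic and private allelic richness, observed and Watterson-expected
    site frequency spectra), differentiation statistics (windowed
    Weir-Cockerham FST for SNPs and VST for CNV read depth), selection
    scans (windowed Tajima's D, H12 haplotype homozygosity with peak
    finding, PCA-based outlier SNPs) with a multi-method consensus, and
    CNV-gene functional-category enrichment with Monte-Carlo chi-squared
    tests. A synthetic-data module generates admixed-cluster selfing
    panels with implanted CNVs, batch-structured exome read depth, and
    selective sweeps so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
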