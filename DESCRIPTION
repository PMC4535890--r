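Package: haplocnv
Title: Quality Control, Merging, LD Binning and Copy-Number Calling for
    Duplicated-Haploid SNP-Array Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for SNP-array data from duplicated
    haploid genomes such as complete hydatidiform moles (CHMs), where every
    locus is expected to be homozygous and genotypes are directly phased
    haplotypes.  Provides haploid-specific genotype quality control that
    derives an intensity reliability threshold from the heterozygosity of
    calls at low relative signal intensity; strand harmonization and
    merging of calls across two array platforms; haploid pairwise r2 and
    greedy LD-bin/tagSNP construction; intensity-only copy-number
    segmentation by circular binary segmentation with a permutation test;
    data-derived loss thresholds from the segment-coverage distribution;
    and cross-platform concordance and merging of copy-number segments
    into copy-number-variation regions.  A seeded synthetic-data generator
    emulates the statistical structure of two-platform duplicated-haploid
    studies (block LD, planted deletions and gains, false heterozygous
    calls in deleted regions, strand flips, duplicate probes) so the whole
    pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
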