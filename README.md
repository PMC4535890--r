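# haplocnv

Quality control, cross-platform merging, LD binning and copy-number
calling for SNP-array data from **duplicated haploid genomes** —
complete hydatidiform moles (CHMs), conceptus tissues carrying two
identical copies of a single sperm genome.  Every locus in such material
is expected homozygous, which changes the analysis in two useful ways:

* genotype calls *are* phased haplotypes ("definitive haplotypes"), so
  pairwise LD can be computed from haplotype counts directly, and
* any heterozygous call is an artifact; hets pile up at low relative
  signal intensity over homozygously deleted (or divergent paralogous)
  regions, giving a haploid-specific QC signal, while the B-allele
  frequency — the usual second CNV channel — carries no information.

The package is aimed at analysts reprocessing two-platform haploid array
studies (a log2R platform "A" and a logRR platform "B") and at method
work that needs a fully testable desk-scale replica of one, via the
built-in synthetic-study generator with known truth.

## What it computes

* **Haploid QC (HQC).**  The het-vs-intensity curve; a reliability
  threshold θ at the 1% heterozygosity level (or a fixed override such
  as log2R −0.6 / logRR −1); forcing het and weak-signal calls to
  no-calls; removal of duplicate-position probes, markers with call rate
  < 90%, and samples not strictly above 96% call rate on both platforms.
* **Strand-harmonized merge.**  Flip detection from allele sets,
  frequency-based orientation of A/T–C/G SNPs with conservative
  exclusion, nucleotide-space comparison of calls, discordant pairs
  forced to no-calls and reported as a discordance fraction.
* **LD bins and tagSNPs.**  Haploid r² from haplotype frequencies
  (`r² = D²/p(1−p)q(1−q)`, D = f − pq) for common SNPs (MAF ≥ 5%)
  within 300 kb; greedy-maximal binning at r² ≥ 0.80; "avesnp" tag
  selection (maximum average r² to the other members).
* **CNV segmentation.**  Circular binary segmentation of each sample ×
  platform × chromosome intensity profile (arc-vs-complement t-like
  statistic, 10,000-permutation acceptance test at α = 0.01, compiled
  core); centromere splitting; the segment-coverage distribution over
  mean-intensity bins; a loss threshold derived from the coverage
  minimum between the deletion mode and the neutral mode (fixed −1/−2
  overrides available); strict loss/"gain > 0.5" classification and the
  > 50 bp size filter.
* **Concordance and CNV regions.**  Per-sample cross-platform overlap at
  ≥ 1 bp, opposite-state tallies, log-length size correlation for
  segments > 10 kb, and state-blind union of all CNV segments into CNV
  regions with the genome fraction they occupy.

## Worked example

```r
library(haplocnv)

# a synthetic two-platform CHM study at the default conditions
sim <- simulate_chm_study(simulation_config(seed = 11))
sim
#> <chm_simulation> 84 samples; platform A: 498 markers, platform B: 513 markers; 45 planted CNV carrier intervals

# the haploid QC signal: hets concentrate at low intensity
curve <- het_intensity_curve(sim$geno_A, sim$intens_A)
find_intensity_threshold(curve)   # derived reliability threshold (log2R)
#> [1] -2.3
autoplot(curve, threshold = -2.3) # het fraction vs intensity

# the whole pipeline with one config and one master seed
res <- run_chm_pipeline(sim, pipeline_config(n_perm = 2000, master_seed = 11))
res
#> <chm_pipeline_result>
#>   samples retained: 84/84
#>   merged markers:   390 (261 shared SNPs, 101 flipped, 0 discordant)
#>   LD bins:          183 (107 singletons)
#>   CNV segments:     A 46, B 45
#>   CNV regions:      4 (27.66% of genome)

bin_summary(res$bins)
#> # A tibble: 1 x 4
#>   n_common_snps n_bins n_singleton_bins fraction_without_proxies
#> 1           390    183              107                    0.274

res$size_correlation
#> # A tibble: 1 x 2
#>   estimate n_pairs
#> 1    0.737      46
```

Reading the output: all 84 samples survive the joint call-rate filter;
101 of the 261 shared SNPs needed a strand flip (the generator plants
flips on ~30% of platform-B SNPs and the merge recovers them from the
annotations); 27% of common SNPs end up without proxies (singleton LD
bins); the ~45 CNV segments per platform are the planted carrier
intervals, they merge into the 4 planted CNV regions, and the log-length
size correlation of overlapped segments reflects the shared truth behind
both platforms.  Because the toy genome is small, those 4 regions cover
a visible share of it — region *counts* and per-genome rates, not the
genome fraction, are the scale-free quantities here.

Every result type has `tidy()`/`glance()` accessors and the main ones
have `autoplot()` methods (het–intensity curve, segment-coverage
profile, cross-platform size agreement).

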