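---
title: "Methods: haploid SNP-array QC, merging, LD binning and CNV calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid SNP-array QC, merging, LD binning and CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Background

Complete hydatidiform moles (CHMs) carry a duplicated haploid genome
derived from a single sperm.  Every locus is expected to be homozygous, so
a SNP array applied to CHM DNA reads out a directly phased haplotype — no
statistical phasing is needed — and the B-allele frequency, the usual
second channel for array CNV calling in diploids, is uninformative.  Two
consequences drive the design of this package:

* **Heterozygous calls are artifacts.**  A genotype caller presented with
  a homozygously deleted (or divergent paralogous) region still emits
  calls, and those calls are enriched for spurious heterozygotes at low
  relative signal intensity.  This is a quality-control signal unique to
  haploid material.
* **Relative signal intensity is the only CNV channel.**  Copy-number
  segmentation must work from the log2-ratio intensities alone (log2R on
  the Affymetrix-style platform "A", logRR on the Illumina-style platform
  "B"), whose scales differ enough that the two platforms must be
  segmented separately and only reconciled at the segment level.

`haplocnv` implements the full desk side of such a study: haploid QC,
cross-platform merge, LD-bin/tagSNP construction, circular binary
segmentation (CBS) with data-derived loss thresholds, and CNV-region
synthesis, plus a seeded generator of synthetic two-platform studies with
known truth.

# Haploid quality control

For every called genotype the paired intensity is binned (bin width
`bin_width = 0.1`, bins `[l, l + 0.1)` anchored at multiples of the
width), and the heterozygous fraction per bin forms the het–intensity
curve.  The reliability threshold $\theta$ is the upper edge of the
highest-intensity bin whose het fraction reaches `het_level` (default 1%),
scanning from low to high intensity; bins without calls are skipped.  A
fixed override (for instance $\theta_A = -0.6$, $\theta_B = -1$, a
conventional log2R/logRR calibration) is accepted anywhere a derived
threshold is.

`apply_hqc()` then forces (i) every heterozygous call and (ii) every call
with intensity strictly below $\theta$ to no-calls — the strictness
follows the convention that a call *at* the threshold is retained.  A het
below $\theta$ is tallied once, as a low-intensity forcing.  Afterwards,
all probes sharing one `(chrom, pos)` are dropped (every member of the
group: with no principled tie-break, keeping an arbitrary one would be a
hidden bias), markers with call rate below 90% are removed (exactly 90%
is kept), and samples are retained only when strictly above 96% call rate
on *both* platforms.  Call-rate filters are computed once on the post-HQC
matrices and applied once, so they are order-insensitive.

# Cross-platform merge

Shared SNPs are matched by `(chrom, pos)`.  Strand harmonization compares
allele sets: equal sets pass, complement-equal sets mark a strand flip and
platform B's annotation is complemented.  Complement-invariant SNPs (A/T
and C/G) cannot be oriented from alleles; the package orients them by
allele-frequency agreement — the orientation minimizing
$|f_A - f_B|$ wins — and *excludes* the SNP when both orientations agree
within `freq_tolerance` (0.1) or when it is rare (MAF < 0.05) on either
platform.  This ambiguity policy is the package's own design choice; the
exclusion default is deliberately conservative because a wrongly oriented
ambiguous SNP corrupts downstream LD silently.

Merging compares calls in nucleotide space (each platform translated
through its harmonized annotation), which also covers annotations that
agree in allele set but swap the a/b order.  Per sample and shared SNP:
two no-calls stay missing, a single call wins, agreement keeps the call,
disagreement forces a no-call and counts as discordant.  The discordance
fraction uses pairs with two non-missing calls as its denominator.  With
independent per-platform opposite-homozygote miscall rate $e$, the
expected discordance is $2e(1-e)$ (both-miscalled pairs agree), an
identity the test suite verifies on synthetic data.

# LD bins and tagSNPs

Because calls are haploid, pairwise LD needs no EM phasing: with
$p$ and $q$ the allele-a frequencies at two markers among jointly called
samples and $f$ their joint frequency,

$$D = f - pq, \qquad r^2 = \frac{D^2}{p(1-p)\,q(1-q)},$$

which equals the squared Pearson correlation of the 0/1 allele indicators
(an equivalence the tests assert against `cor()` on random instances).
Pairs are restricted to common SNPs (MAF $\ge$ 5% over non-missing merged
calls — the only frequency available), the same chromosome, and at most
300 kb separation; the window is applied at pair computation.  Pairs
monomorphic among their jointly called samples are skipped.

Binning is greedy-maximal: repeatedly seed at the unbinned marker with the
most unbinned neighbours at $r^2 \ge 0.80$, take seed plus neighbours as a
bin, remove them, and stop when no neighbours remain; the rest are
singleton bins ("SNPs without proxies").  Ties in the neighbour count are
broken by smaller genomic position, then marker id — the tie-break is the
package's own, chosen for determinism.  Each bin's tagSNP is the member
with maximal average $r^2$ to the other members ("avesnp"); member pairs
missing from the pair table (beyond the window) contribute zero to that
average, and a singleton tags itself.  The fraction of common SNPs without
proxies equals singleton bins over common SNPs, the identity behind the
published 17%.

# CNV segmentation

## The CBS core

For one sample, platform and chromosome the ordered non-missing
intensities $x_1..x_n$ are segmented recursively.  Candidate changes are
arcs $(i, j]$; the statistic is the two-sample $t$-like contrast

$$T(i,j) = \frac{|\bar{x}_{\text{arc}} - \bar{x}_{\text{rest}}|}
{s\sqrt{1/k + 1/(n-k)}}$$

with $s$ the segment's overall (population) standard deviation and both
parts at least `min_width = 2` markers.  The maximizing arc is accepted
when its permutation p-value — the share of `n_perm = 10000` random
permutations of the segment's values whose best-split statistic reaches
the observed one — is at most `alpha = 0.01`; accepted cuts recurse.
These pinned values (no smoothing, no split-undoing) play the role of the
classical CBS defaults; pinning them explicitly keeps reruns reproducible
without depending on any historical implementation's internals.  Two
numerical points worth noting:

* complementary arcs ($i=0$ vs $j=n$ around the same cut) have identical
  statistics, so only the implied cut set is well-defined; the compiled
  maximizer and the brute-force oracle in the tests are compared on cut
  sets.
* the permutation loop (compiled, Fisher–Yates on R's RNG) exits early
  once the exceedance count proves $p > \alpha$, which makes
  change-point-free profiles cheap while true change points pay the full
  permutation cost.  Permutation RNG is seeded per
  `(platform, sample, chromosome)` by a stable string hash combined with
  the master seed, so results are independent of execution order.

Segment coordinates span the first to last contributing marker;
inter-marker gaps at segment edges belong to no segment.

## Thresholds and filtering

Segments overlapping a centromere are split at its boundaries, each part
re-snapped to its remaining markers' span with its mean recomputed, and
empty parts dropped.  The bp length of every segment is then accumulated
into mean-intensity bins (width 0.1).  In haploid material this
distribution is bimodal: a deletion peak well below zero and the main
neutral peak at zero.  The loss threshold is operationalized as the upper
edge of the minimum-coverage bin strictly between the mode of the
lowest-intensity contiguous covered run and the main mode — the plateau
of the cumulative coverage curve.  Ties across an empty stretch resolve
to the middle bin of the minimal run, which maximizes the margin to both
modes.  With nothing separated below zero the $-\infty$ sentinel is
returned (no losses); a profile with a low mode but no mode near zero
cannot be bracketed and errors.  Fixed overrides (−1 for log2R, −2 for
logRR) reproduce a conventional calibration exactly.

Classification is strict: mean < loss threshold is a loss, mean > 0.5 a
gain (the gain boundary is not derivable from the coverage profile and is
set by convention; strictness mirrors the loss rule), all else neutral.
Segments of any state with length ≤ 50 bp are removed; the filter runs
after centromere splitting.

# Concordance and CNV regions

Per sample, a platform-A CNV segment counts as overlapped when ≥ 1 bp
(configurable) of it intersects a platform-B CNV segment; gain-vs-loss
overlaps are tallied separately.  Overlap arithmetic is on 1-based closed
intervals, length $\min(e_A, e_B) - \max(s_A, s_B) + 1$.  The size
correlation is the Pearson correlation of log10 lengths over overlapped
pairs with both segments strictly longer than 10 kb (undefined below 3
pairs).  CNV regions are the union of all CNV segments across samples and
platforms ignoring state; bookended intervals merge by default because
marker-span boundaries make 1-bp gaps artifacts of probe spacing (a flag
restores strict-overlap merging).  The union is delegated to
`GenomicRanges::reduce()`.  Region merging is idempotent, and the genome
fraction is total region bp over total genome bp.

# The synthetic study generator

The generator emulates the statistical structure the pipeline exploits,
at desk scale, with one mandatory seed (identical seeds give
byte-identical studies):

* **Duplicated haploidy** — one haplotype per sample, reported as
  homozygous calls.
* **Block LD** — per block, samples copy whole-block haplotypes from an
  ancestral pool (default 6) with light per-site mutation (0.005).  Sites
  within a block share a few pool partition patterns (default 3, with a
  0.25 chance of a fresh random pattern per site), which is what produces
  high within-block $r^2$, near-zero between-block $r^2$, and a realistic
  minority of SNPs without proxies; a pool-MAF floor of 0.05 keeps sites
  common.  This is a copying model, not a coalescent: the pipeline needs
  tunable block LD, not realistic genealogies.
* **Two platforms** — each SNP site lands on each platform independently
  with probability 0.8 (partial overlap), plus per-platform
  intensity-only probes; 30% of platform-B SNPs are annotated on the
  opposite strand; a few duplicate-position probes are injected into
  platform B; optionally A/T–C/G sites exercise the ambiguity policy.
* **CNVs and intensities** — planted loss/gain intervals with per-CNV
  carrier fractions; carrier markers get the platform's mean shift
  (defaults: losses −3 on A, −4 on B, mirroring the two platforms'
  distinct loss scales; gains $\log_2(3/2) \approx 0.58$, one extra copy)
  plus Gaussian noise (0.25 / 0.2), and a small missing-intensity rate.
* **Call errors** — outside deletions the true allele is reported with a
  0.005 no-call rate and a tiny opposite-homozygote miscall rate
  (default $5\times10^{-6}$, chosen so that residual cross-platform
  discordance is of the order published for real duplicated-haploid
  data); inside a carried deletion a heterozygous call is fabricated with
  probability 0.3, reproducing the het-at-low-intensity artifact.

Default scale is 84 samples — the size of a retained CHM cohort — on a
two-chromosome genome of 32 LD blocks (15 SNPs per 50-kb block) around
marker-free centromeres, with two losses and two gains at carrier
fractions 0.06–0.2.  This keeps a full pipeline run (including 10,000
permutations per accepted split) in the minutes range on one core.  What
the generator does *not* emulate: genome-scale CNV rarity (planted CNVs
cover a visible share of the toy genome, so region genome-fractions are
far larger than the ~1% of a real genome), raw probe-level intensity
behaviour (GC waves, batch effects), recombination maps and demography.
Passing tests therefore demonstrate correctness of the algorithms under
the generated structure, not field performance on real arrays.

# Problem sizes used by the tests

Unit tests run on hand-built cases and 8–40-sample simulations; the
oracle suites use 200–1000 random small instances (CBS brute force at
≤ 50 markers, $r^2$ against `cor()`), 200 pure-noise profiles of 100
markers for type-I control, 20 seeded 4-sample genomes for loss recovery,
and 20 seeds for strand-flip recovery.  These sizes are the package's
choice of a thorough-but-quick regime; all thresholds asserted by the
tests (breakpoint error ≤ 2 markers, type-I ≤ 5% at $\alpha = 0.01$,
discordance within 3 binomial SDs of $2e(1-e)$) are fixed properties of
the method, not tuned values.

# Known limitations

* The loss-threshold rule needs a separated deletion mode; profiles whose
  deletion segments blend into the neutral peak (heavy noise, tiny
  shifts) fall back to errors or the $-\infty$ sentinel rather than
  guessing.
* Divergent-paralog heterozygosity is not distinguished from
  deletion-driven heterozygosity; both are forced to no-calls.
* Ambiguous-strand SNPs are excluded rather than rescued by external
  references (no rsID matching; markers are matched by position only).
* Multi-state copy-number models (HMMs), GC correction and
  B-allele-frequency evidence are out of scope by design.
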