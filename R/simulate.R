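# Seeded generator for two-platform duplicated-haploid (CHM-like) studies.
# Each sample is a single haplotype reported as homozygous genotypes; LD is
# block-structured (haplotype-pool copying model); deletions/gains are
# planted intervals that displace marker intensity; false heterozygous
# calls are emitted inside carried deletions, reproducing the het-at-low-
# intensity artifact the haploid QC stage exploits.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Configuration for the synthetic two-platform CHM study
#'
#' Defaults describe the study conditions the pipeline is developed
#' against: 84 retained duplicated-haploid samples, block-structured LD
#' among common SNPs, two platforms with partially overlapping marker
#' panels and different intensity scales (log2R vs logRR), planted
#' polymorphic losses and gains, strand flips on a subset of shared SNPs,
#' duplicate-position probes on platform B, and low baseline error rates.
#' The genome itself is scaled down (two chromosomes of LD blocks around a
#' marker-free centromere) so a full run remains quick; scale parameters,
#' not structure, change at full size.
#'
#' @param n_samples Number of duplicated-haploid samples.
#' @param n_chroms Number of simulated chromosomes (`chr1`, `chr2`, ...).
#' @param n_blocks Total number of LD blocks, split evenly across
#'   chromosomes (half on each arm).
#' @param snps_per_block SNP sites per block.
#' @param block_span_bp Genomic span of one block, bp.
#' @param n_haplotypes_per_block Ancestral pool size per block; samples copy
#'   whole-block haplotypes from this pool, which is what creates high
#'   within-block and near-zero between-block r2.
#' @param n_pool_patterns Number of shared pool partition patterns per
#'   block; sites drawing the same pattern are in perfect pool LD.
#' @param pattern_noise Probability that a site deviates from the shared
#'   patterns to a fresh random one (such sites tend to lack proxies).
#' @param maf_floor Minimum minor-allele frequency in the ancestral pool.
#' @param mutation_rate Per-site probability that a copied allele is
#'   flipped, decorrelating sites within a block.
#' @param platform_snp_fraction Fraction of SNP sites carried by each
#'   platform (drawn independently, so panels overlap partially).
#' @param intensity_probes_per_chrom Intensity-only (copy-number) probes
#'   per chromosome per platform.
#' @param cnv_spec Tibble with columns `chrom`, `start`, `end`, `kind`
#'   (`"loss"`/`"gain"`), `carrier_fraction`; `NULL` uses a default of two
#'   losses and two gains placed on block intervals.
#' @param noise_sd_A,noise_sd_B Intensity noise SD per platform
#'   (log2-ratio scale).
#' @param loss_shift_A,loss_shift_B,gain_shift_A,gain_shift_B Mean
#'   intensity displacement of CNV carriers.  Loss shifts are strongly
#'   negative (homozygous deletion of a haploid locus leaves no signal);
#'   the default gain shift is `log2(3/2)` (one extra copy).
#' @param false_het_rate_in_loss Probability that a SNP call inside a
#'   carried loss is emitted as heterozygous (the artifact of calling
#'   genotypes where no template remains).
#' @param baseline_nocall_rate,baseline_miscall_rate Per-call no-call and
#'   opposite-homozygote miscall probabilities outside deletions.
#' @param missing_intensity_rate Per-cell probability of a missing
#'   intensity value.
#' @param strand_flip_fraction Fraction of shared-capable platform-B SNPs
#'   whose platform-B annotation is reported on the opposite strand.
#' @param ambiguous_snp_fraction Fraction of SNP sites given
#'   complement-invariant (A/T or C/G) allele pairs; 0 by default, set > 0
#'   to exercise the merge stage's ambiguity policy.
#' @param duplicate_probe_count Number of duplicate-position probes
#'   injected into platform B.
#' @param seed Mandatory RNG seed; derived stage seeds are `seed + 1` and
#'   `seed + 2`, so keep it below `2^31 - 3`.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_samples = 84,
                              n_chroms = 2,
                              n_blocks = 32,
                              snps_per_block = 15,
                              block_span_bp = 50000,
                              n_haplotypes_per_block = 6,
                              n_pool_patterns = 3,
                              pattern_noise = 0.25,
                              maf_floor = 0.05,
                              mutation_rate = 0.005,
                              platform_snp_fraction = 0.8,
                              intensity_probes_per_chrom = 60,
                              cnv_spec = NULL,
                              noise_sd_A = 0.25, noise_sd_B = 0.2,
                              loss_shift_A = -3, loss_shift_B = -4,
                              gain_shift_A = log2(3 / 2),
                              gain_shift_B = log2(3 / 2),
                              false_het_rate_in_loss = 0.3,
                              baseline_nocall_rate = 0.005,
                              baseline_miscall_rate = 5e-6,
                              missing_intensity_rate = 0.01,
                              strand_flip_fraction = 0.3,
                              ambiguous_snp_fraction = 0,
                              duplicate_probe_count = 4,
                              seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_chroms = n_chroms, n_blocks = n_blocks,
    snps_per_block = snps_per_block, block_span_bp = block_span_bp,
    n_haplotypes_per_block = n_haplotypes_per_block,
    n_pool_patterns = n_pool_patterns, pattern_noise = pattern_noise,
    maf_floor = maf_floor, mutation_rate = mutation_rate,
    platform_snp_fraction = platform_snp_fraction,
    intensity_probes_per_chrom = intensity_probes_per_chrom,
    cnv_spec = cnv_spec,
    noise_sd_A = noise_sd_A, noise_sd_B = noise_sd_B,
    loss_shift_A = loss_shift_A, loss_shift_B = loss_shift_B,
    gain_shift_A = gain_shift_A, gain_shift_B = gain_shift_B,
    false_het_rate_in_loss = false_het_rate_in_loss,
    baseline_nocall_rate = baseline_nocall_rate,
    baseline_miscall_rate = baseline_miscall_rate,
    missing_intensity_rate = missing_intensity_rate,
    strand_flip_fraction = strand_flip_fraction,
    ambiguous_snp_fraction = ambiguous_snp_fraction,
    duplicate_probe_count = duplicate_probe_count,
    seed = seed
  )
  probs <- c("maf_floor", "mutation_rate", "platform_snp_fraction",
             "false_het_rate_in_loss", "baseline_nocall_rate",
             "baseline_miscall_rate", "missing_intensity_rate",
             "strand_flip_fraction", "ambiguous_snp_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (loss_shift_A >= 0 || loss_shift_B >= 0) stop("loss shifts must be negative")
  if (gain_shift_A <= 0 || gain_shift_B <= 0) stop("gain shifts must be positive")
  if (is.null(cfg$cnv_spec)) cfg$cnv_spec <- default_cnv_spec(cfg)
  cfg$cnv_spec <- tibble::as_tibble(cfg$cnv_spec)
  structure(cfg, class = "sim_config")
}

# chromosome layout: blocks_per_chrom blocks of block_span_bp, a marker-free
# centromere between the two halves, 10 kb telomeric margins
sim_layout <- function(config) {
  bpc <- config$n_blocks %/% config$n_chroms
  if (bpc < 1) stop("need at least one block per chromosome")
  cen_len <- 30000L
  margin <- 10000L
  span <- as.integer(config$block_span_bp)
  half <- bpc %/% 2
  blocks <- purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
    starts <- margin + (seq_len(bpc) - 1L) * span + 1L
    shift <- ifelse(seq_len(bpc) > half, cen_len, 0L)
    tibble::tibble(
      chrom = paste0("chr", ci), block = seq_len(bpc),
      start = starts + shift, end = starts + shift + span - 1L
    )
  })
  cen_start <- margin + half * span + 1L
  genome <- tibble::tibble(
    chrom = paste0("chr", seq_len(config$n_chroms)),
    length_bp = margin + bpc * span + cen_len + margin,
    centromere_start = cen_start,
    centromere_end = cen_start + cen_len - 1L
  )
  list(blocks = blocks, genome = genome)
}

# two losses and two gains of deliberately different sizes (so segment-size
# agreement between platforms is informative), polymorphic in the cohort
default_cnv_spec <- function(config) {
  lay <- sim_layout(config)
  b <- lay$blocks
  span <- function(chrom, from_block, to_block, frac = 1) {
    bb <- b[b$chrom == chrom & b$block >= from_block & b$block <= to_block, ]
    s <- min(bb$start)
    c(s, s + round(frac * (max(bb$end) - s + 1)) - 1)
  }
  bpc <- config$n_blocks %/% config$n_chroms
  if (config$n_chroms < 2 || bpc < 8) {
    iv <- span("chr1", 2, min(3, bpc))
    return(tibble::tibble(chrom = "chr1", start = iv[1], end = iv[2],
                          kind = "loss", carrier_fraction = 0.2))
  }
  q1 <- span("chr1", 3, 5)                    # 3 blocks
  q2 <- span("chr1", bpc - 3, bpc - 3)        # 1 block
  q3 <- span("chr2", 5, 6, frac = 0.75)       # 1.5 blocks
  q4 <- span("chr2", bpc - 3, bpc)            # 4 blocks
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(q1[1], q2[1], q3[1], q4[1]),
    end = c(q1[2], q2[2], q3[2], q4[2]),
    kind = c("loss", "gain", "loss", "gain"),
    carrier_fraction = c(0.2, 0.12, 0.15, 0.06)
  )
}

#' Simulate block-LD haplotypes and the two platform marker panels
#'
#' Per block, each sample copies one haplotype from an ancestral pool of
#' `n_haplotypes_per_block`, with per-site mutation; this yields high
#' within-block r2 and approximately zero r2 between blocks.  Each SNP site
#' is carried by platform A and/or platform B independently with
#' probability `platform_snp_fraction`; a fraction of platform-B SNPs has
#' its annotation complemented (strand flip).  Intensity-only probes are
#' laid uniformly over each chromosome's arms.
#'
#' Sets the RNG seed to `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `ann_A`/`ann_B` (marker annotations), `sites` (the
#'   site table with ref/alt alleles and platform membership),
#'   `haplotypes` (samples x sites nucleotide matrix), `genome` (metadata
#'   tibble) and `flipped_marker_ids`.
#' @export
simulate_haplotypes <- function(config) {
  set.seed(config$seed)
  lay <- sim_layout(config)
  n_pool <- config$n_haplotypes_per_block
  lo <- ceiling(config$maf_floor * n_pool)
  hi <- floor(n_pool / 2)
  if (hi < 1) {
    if (config$maf_floor > 0) {
      stop("maf_floor ", config$maf_floor, " unattainable with pool size ", n_pool)
    }
  } else if (lo > hi) {
    stop("maf_floor ", config$maf_floor, " unattainable with pool size ", n_pool)
  }

  nt <- c("A", "C", "G", "T")
  blocks <- lay$blocks
  site_rows <- list()
  hap_cols <- list()
  sid <- 0L
  for (k in seq_len(nrow(blocks))) {
    bk <- blocks[k, ]
    pos <- sort(sample(seq.int(bk$start, bk$end), config$snps_per_block))
    m <- config$snps_per_block
    # ancestral pool: 0 = ref, 1 = alt, minor count within [lo, hi].  Sites
    # share a few pool partition patterns (descent within the block), which
    # is what makes within-block r2 high; a site deviates to a fresh random
    # pattern with probability pattern_noise, and such sites tend to end up
    # as SNPs without proxies.
    pool <- matrix(0L, nrow = n_pool, ncol = m)
    if (hi >= 1) {
      draw_pattern <- function() {
        p <- integer(n_pool)
        p[sample(n_pool, sample(seq.int(max(lo, 1L), hi), 1))] <- 1L
        p
      }
      base <- replicate(max(1L, config$n_pool_patterns), draw_pattern(),
                        simplify = FALSE)
      for (j in seq_len(m)) {
        pool[, j] <- if (stats::runif(1) < config$pattern_noise) {
          draw_pattern()
        } else {
          base[[sample(length(base), 1)]]
        }
      }
    }
    idx <- sample(n_pool, config$n_samples, replace = TRUE)
    hap01 <- pool[idx, , drop = FALSE]
    if (config$mutation_rate > 0) {
      mut <- matrix(stats::runif(length(hap01)) < config$mutation_rate,
                    nrow = nrow(hap01))
      hap01[mut] <- 1L - hap01[mut]
    }
    ambiguous <- stats::runif(m) < config$ambiguous_snp_fraction
    ref <- character(m); alt <- character(m)
    for (j in seq_len(m)) {
      if (ambiguous[j]) {
        pair <- if (stats::runif(1) < 0.5) c("A", "T") else c("C", "G")
        if (stats::runif(1) < 0.5) pair <- rev(pair)
      } else {
        repeat {
          pair <- sample(nt, 2)
          if (COMPLEMENT[pair[1]] != pair[2]) break
        }
      }
      ref[j] <- pair[1]; alt[j] <- pair[2]
    }
    site_rows[[k]] <- tibble::tibble(
      site = sid + seq_len(m), chrom = bk$chrom, pos = pos, block = bk$block,
      ref = ref, alt = alt, ambiguous = ambiguous
    )
    hap_cols[[k]] <- hap01
    sid <- sid + m
  }
  sites <- dplyr::bind_rows(site_rows)
  hap01 <- do.call(cbind, hap_cols)
  samples <- sprintf("CHM%03d", seq_len(config$n_samples))
  haplotypes <- matrix(ifelse(hap01 == 0L, rep(sites$ref, each = config$n_samples),
                              rep(sites$alt, each = config$n_samples)),
                       nrow = config$n_samples,
                       dimnames = list(samples, sprintf("S%05d", sites$site)))

  sites$on_A <- stats::runif(nrow(sites)) < config$platform_snp_fraction
  sites$on_B <- stats::runif(nrow(sites)) < config$platform_snp_fraction
  # strand flips: a fraction of platform-B SNPs annotated on the other strand
  sites$flipped <- FALSE
  idx_B <- which(sites$on_B)
  n_flip <- round(config$strand_flip_fraction * length(idx_B))
  if (n_flip > 0) sites$flipped[sample(idx_B, n_flip)] <- TRUE

  io_probes <- function(platform) {
    purrr::map_dfr(seq_len(nrow(lay$genome)), function(ci) {
      g <- lay$genome[ci, ]
      arms <- c(seq.int(10000L, g$centromere_start - 1L),
                seq.int(g$centromere_end + 1L, g$length_bp - 10000L))
      pos <- sort(sample(arms, config$intensity_probes_per_chrom))
      tibble::tibble(chrom = g$chrom, pos = pos)
    })
  }
  snp_ann <- function(platform) {
    on <- if (platform == "A") sites$on_A else sites$on_B
    s <- sites[on, ]
    a <- s$ref; b <- s$alt
    if (platform == "B") {
      fl <- s$flipped
      a[fl] <- COMPLEMENT[a[fl]]; b[fl] <- COMPLEMENT[b[fl]]
    }
    tibble::tibble(
      marker_id = sprintf("%s_S%05d", platform, s$site),
      chrom = s$chrom, pos = s$pos, allele_a = a, allele_b = b,
      probe_class = "snp", platform = platform
    )
  }
  ann_A <- dplyr::bind_rows(
    snp_ann("A"),
    {
      p <- io_probes("A")
      tibble::tibble(marker_id = sprintf("A_CN%05d", seq_len(nrow(p))),
                     chrom = p$chrom, pos = p$pos, allele_a = "", allele_b = "",
                     probe_class = "intensity_only", platform = "A")
    }
  )
  ann_B <- dplyr::bind_rows(
    snp_ann("B"),
    {
      p <- io_probes("B")
      tibble::tibble(marker_id = sprintf("B_IO%05d", seq_len(nrow(p))),
                     chrom = p$chrom, pos = p$pos, allele_a = "", allele_b = "",
                     probe_class = "intensity_only", platform = "B")
    }
  )
  # duplicate-position probes injected into platform B: a second probe at an
  # existing SNP position (same alleles, new id)
  dup_ids <- character(0)
  dup_src <- character(0)
  ndup <- min(config$duplicate_probe_count, sum(sites$on_B))
  if (ndup > 0) {
    b_snps <- which(ann_B$probe_class == "snp")
    src <- sample(b_snps, ndup)
    dup <- ann_B[src, ]
    dup$marker_id <- sprintf("B_DUP%03d", seq_len(ndup))
    dup_ids <- dup$marker_id
    dup_src <- ann_B$marker_id[src]
    ann_B <- dplyr::bind_rows(ann_B, dup)
  }
  flipped_ids <- sprintf("B_S%05d", sites$site[sites$flipped & sites$on_B])
  # duplicate probes inherit their source's strand
  flipped_ids <- c(flipped_ids, dup_ids[dup_src %in% flipped_ids])
  list(
    ann_A = sort_annotation(ann_A), ann_B = sort_annotation(ann_B),
    sites = sites, haplotypes = haplotypes, genome = lay$genome,
    flipped_marker_ids = flipped_ids,
    duplicate_marker_ids = dup_ids,
    dup_src = stats::setNames(dup_src, dup_ids)
  )
}

# carrier matrix: for each sample x platform marker, the planted CNV kind
# ("" = none); also draws the carrier sets and checks for opposite-kind
# overlaps in one carrier
draw_carriers <- function(config, sim) {
  cnv <- config$cnv_spec
  samples <- rownames(sim$haplotypes)
  carriers <- purrr::map_dfr(seq_len(nrow(cnv)), function(i) {
    n_car <- round(cnv$carrier_fraction[i] * length(samples))
    if (n_car == 0) return(tibble::tibble())
    tibble::tibble(cnv_id = i, chrom = cnv$chrom[i], start = cnv$start[i],
                   end = cnv$end[i], kind = cnv$kind[i],
                   sample_id = sample(samples, n_car))
  })
  if (!nrow(carriers)) {
    carriers <- tibble::tibble(cnv_id = integer(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               kind = character(0), sample_id = character(0))
  }
  if (nrow(carriers)) {
    ov <- dplyr::inner_join(carriers, carriers, by = c("sample_id", "chrom"),
                            relationship = "many-to-many")
    bad <- ov$cnv_id.x < ov$cnv_id.y & ov$start.x <= ov$end.y &
      ov$start.y <= ov$end.x & ov$kind.x != ov$kind.y
    if (any(bad)) {
      stop("overlapping planted CNVs of opposite kind in sample ",
           ov$sample_id[bad][1])
    }
  }
  carriers
}

#' Plant CNV intensity shifts and per-marker noise
#'
#' For each platform, carrier markers inside a planted CNV get the
#' platform's loss or gain mean shift; everything else has mean zero.
#' Gaussian noise with the platform's SD is added, and a small fraction of
#' cells is set missing.  Sets the RNG seed to `config$seed + 1`, so the
#' carrier draw and noise are reproducible independently of the haplotype
#' stage.
#'
#' @param config A [simulation_config()].
#' @param sim Result of [simulate_haplotypes()].
#' @return List with `intens_A`, `intens_B` ([intensity_matrix()]s over all
#'   platform markers) and `cnv_carriers` (the per-sample truth intervals).
#' @export
plant_cnvs_and_intensities <- function(config, sim) {
  set.seed(config$seed + 1)
  carriers <- draw_carriers(config, sim)
  samples <- rownames(sim$haplotypes)
  one_platform <- function(ann, noise_sd, loss_shift, gain_shift) {
    m <- matrix(stats::rnorm(length(samples) * nrow(ann), sd = noise_sd),
                nrow = length(samples),
                dimnames = list(samples, ann$marker_id))
    if (nrow(carriers)) {
      for (i in seq_len(nrow(carriers))) {
        cr <- carriers[i, ]
        in_cnv <- ann$chrom == cr$chrom & ann$pos >= cr$start & ann$pos <= cr$end
        shift <- if (cr$kind == "loss") loss_shift else gain_shift
        m[cr$sample_id, in_cnv] <- m[cr$sample_id, in_cnv] + shift
      }
    }
    if (config$missing_intensity_rate > 0) {
      m[stats::runif(length(m)) < config$missing_intensity_rate] <- NA_real_
    }
    intensity_matrix(m)
  }
  list(
    intens_A = one_platform(sim$ann_A, config$noise_sd_A,
                            config$loss_shift_A, config$gain_shift_A),
    intens_B = one_platform(sim$ann_B, config$noise_sd_B,
                            config$loss_shift_B, config$gain_shift_B),
    cnv_carriers = carriers
  )
}

#' Emit genotype calls from the true haplotypes
#'
#' Outside carried deletions a SNP call reports the sample's true allele as
#' a homozygote, with a baseline no-call rate and a baseline
#' opposite-homozygote miscall rate.  Inside a carried deletion there is no
#' template, and the caller fabricates a heterozygous call with probability
#' `false_het_rate_in_loss`; because in-deletion markers also have strongly
#' negative intensity, realized heterozygosity is concentrated at low
#' signal intensity.  Duplicate-position probes are called independently
#' from the same underlying allele.  Sets the RNG seed to
#' `config$seed + 2`.
#'
#' @inheritParams plant_cnvs_and_intensities
#' @param cnv_carriers Truth carrier tibble from
#'   [plant_cnvs_and_intensities()].
#' @return List with `geno_A`, `geno_B` ([genotype_matrix()]s over each
#'   platform's SNP probes).
#' @export
emit_genotype_calls <- function(config, sim, cnv_carriers) {
  set.seed(config$seed + 2)
  samples <- rownames(sim$haplotypes)
  losses <- cnv_carriers[cnv_carriers$kind == "loss", , drop = FALSE]
  one_platform <- function(ann) {
    snp <- ann[ann$probe_class == "snp", ]
    site_idx <- integer(nrow(snp))
    is_dup <- grepl("^B_DUP", snp$marker_id)
    site_idx[!is_dup] <- as.integer(sub("^[AB]_S", "", snp$marker_id[!is_dup]))
    if (any(is_dup)) {
      src <- sim$dup_src[snp$marker_id[is_dup]]
      site_idx[is_dup] <- as.integer(sub("^B_S", "", src))
    }
    ord <- match(site_idx, sim$sites$site)
    true_is_ref <- sim$haplotypes[, ord, drop = FALSE] ==
      matrix(sim$sites$ref[ord], nrow = length(samples), ncol = nrow(snp),
             byrow = TRUE)
    calls <- ifelse(true_is_ref, "AA", "BB")
    # baseline errors
    u <- matrix(stats::runif(length(calls)), nrow = nrow(calls))
    mis <- u < config$baseline_miscall_rate
    calls[mis] <- ifelse(calls[mis] == "AA", "BB", "AA")
    u2 <- matrix(stats::runif(length(calls)), nrow = nrow(calls))
    calls[u2 < config$baseline_nocall_rate] <- "NC"
    # false hets inside carried losses
    if (nrow(losses)) {
      for (i in seq_len(nrow(losses))) {
        cr <- losses[i, ]
        in_loss <- snp$chrom == cr$chrom & snp$pos >= cr$start & snp$pos <= cr$end
        if (!any(in_loss)) next
        r <- match(cr$sample_id, samples)
        u3 <- stats::runif(sum(in_loss))
        calls[r, in_loss][u3 < config$false_het_rate_in_loss] <- "AB"
      }
    }
    dimnames(calls) <- list(samples, snp$marker_id)
    genotype_matrix(calls)
  }
  list(geno_A = one_platform(sim$ann_A), geno_B = one_platform(sim$ann_B))
}

#' Run the full synthetic study
#'
#' Chains [simulate_haplotypes()], [plant_cnvs_and_intensities()] and
#' [emit_genotype_calls()] and bundles annotations, call and intensity
#' matrices, genome metadata and the ground truth.  Identical seeds give
#' byte-identical simulations.
#'
#' @param config A [simulation_config()].
#' @return A `chm_simulation` list with elements `config`, `ann_A`,
#'   `ann_B`, `geno_A`, `geno_B`, `intens_A`, `intens_B`, `genome` and
#'   `truth` (haplotypes, site table, CNV carriers, flipped and duplicate
#'   marker ids).
#' @export
simulate_chm_study <- function(config = simulation_config()) {
  sim <- simulate_haplotypes(config)
  pl <- plant_cnvs_and_intensities(config, sim)
  gn <- emit_genotype_calls(config, sim, pl$cnv_carriers)
  structure(list(
    config = config,
    ann_A = sim$ann_A, ann_B = sim$ann_B,
    geno_A = gn$geno_A, geno_B = gn$geno_B,
    intens_A = pl$intens_A, intens_B = pl$intens_B,
    genome = sim$genome,
    truth = list(
      haplotypes = sim$haplotypes, sites = sim$sites,
      cnv_carriers = pl$cnv_carriers,
      flipped_marker_ids = sim$flipped_marker_ids,
      duplicate_marker_ids = sim$duplicate_marker_ids,
      dup_src = sim$dup_src
    )
  ), class = "chm_simulation")
}

#' @export
print.chm_simulation <- function(x, ...) {
  cat("<chm_simulation> ", x$config$n_samples, " samples; platform A: ",
      nrow(x$ann_A), " markers, platform B: ", nrow(x$ann_B), " markers; ",
      nrow(x$truth$cnv_carriers), " planted CNV carrier intervals\n", sep = "")
  invisible(x)
}

#' Write a simulation to the pipeline's text formats
#'
#' Emits per-platform annotation, genotype and intensity TSVs, the genome
#' metadata table, and a `truth_*` set of TSVs for test harnesses.
#'
#' @param study A `chm_simulation`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_marker_annotation(study$ann_A, p("annotation_A.tsv"))
  write_marker_annotation(study$ann_B, p("annotation_B.tsv"))
  write_matrix(study$geno_A, p("genotypes_A.tsv"))
  write_matrix(study$geno_B, p("genotypes_B.tsv"))
  write_matrix(study$intens_A, p("intensity_A.tsv"))
  write_matrix(study$intens_B, p("intensity_B.tsv"))
  write_genome_metadata(study$genome, p("genome.tsv"))
  utils::write.table(study$truth$cnv_carriers, p("truth_cnv_carriers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = study$truth$flipped_marker_ids),
    p("truth_flipped_markers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
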