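# End-to-end orchestration: HQC per platform -> joint sample filter ->
# strand reconciliation and merge -> LD binning -> per-platform CBS
# segmentation and classification -> cross-platform concordance and CNV
# regions.  One config object holds every stage parameter; a master seed
# drives all randomness.

#' Pipeline configuration
#'
#' All stage parameters in one serializable list.  `threshold_A/B` and
#' `loss_threshold_A/B` default to `NULL`, meaning the thresholds are
#' derived from the data (het-intensity curve; segment-coverage profile);
#' fixed overrides of -0.6/-1 (HQC) and -1/-2 (loss) reproduce a
#' conventional log2R/logRR calibration exactly.
#'
#' @param het_level Het fraction marking unreliable calls, default 0.01.
#' @param bin_width Intensity bin width for curves/profiles, default 0.1.
#' @param threshold_A,threshold_B Fixed HQC intensity thresholds
#'   (`NULL` = derive).
#' @param marker_min Minimum marker call rate, default 0.90.
#' @param sample_min Joint sample call-rate bound (strict), default 0.96.
#' @param freq_tolerance,rare_maf Ambiguous-SNP orientation policy, see
#'   [reconcile_strands()].
#' @param maf_min,window_bp,r2_threshold LD-binning parameters
#'   (0.05 / 300 kb / 0.80).
#' @param alpha,n_perm,min_width CBS parameters (0.01 / 10000 / 2).
#' @param loss_threshold_A,loss_threshold_B Fixed loss thresholds
#'   (`NULL` = derive from the coverage profile).
#' @param gain_threshold Gain boundary, default 0.5.
#' @param min_size_bp Minimum CNV-segment size (strictly greater kept),
#'   default 50.
#' @param min_overlap_bp Concordance overlap, default 1.
#' @param size_corr_min_bp Size-correlation length cut, default 10000.
#' @param merge_bookended Merge bookended intervals into one region,
#'   default `TRUE`.
#' @param master_seed Master seed for all stage RNG.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(het_level = 0.01, bin_width = 0.1,
                            threshold_A = NULL, threshold_B = NULL,
                            marker_min = 0.90, sample_min = 0.96,
                            freq_tolerance = 0.1, rare_maf = 0.05,
                            maf_min = 0.05, window_bp = 300000,
                            r2_threshold = 0.80,
                            alpha = 0.01, n_perm = 10000, min_width = 2,
                            loss_threshold_A = NULL, loss_threshold_B = NULL,
                            gain_threshold = 0.5, min_size_bp = 50,
                            min_overlap_bp = 1, size_corr_min_bp = 10000,
                            merge_bookended = TRUE, master_seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$het_level > 0, cfg$bin_width > 0,
            cfg$marker_min >= 0, cfg$marker_min <= 1,
            cfg$sample_min >= 0,
            cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_perm >= 1,
            cfg$min_width >= 1, cfg$min_size_bp >= 0,
            cfg$min_overlap_bp >= 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(pipeline_config, vals)
}

#' Run the whole pipeline
#'
#' Stages execute in order: haploid QC on each platform, the joint
#' both-platform sample filter, strand reconciliation and merge, LD
#' binning on the merged haploid calls, CBS segmentation of each
#' platform's intensities for the retained samples, loss-threshold
#' derivation and segment classification, and cross-platform concordance
#' plus CNV-region merging.  With `outdir` set, each stage's tables are
#' written (TSV/BED) before the next stage runs and MD5 checksums are
#' recorded in the manifest.
#'
#' @param data A `chm_simulation` or any list with elements `ann_A`,
#'   `ann_B`, `geno_A`, `geno_B`, `intens_A`, `intens_B`, `genome`.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return A `chm_pipeline_result` list: per-stage results (`hqc_A`,
#'   `hqc_B`, `merge`, `bins`, `segments_A`, `segments_B`, `cnv_segments`,
#'   `concordance`, `size_correlation`, `regions`, `genome_fraction`) and
#'   a `manifest` with parameters, per-stage record counts and output
#'   checksums.
#' @export
run_chm_pipeline <- function(data, config = pipeline_config(),
                             outdir = NULL) {
  emit <- function(name, writer) {
    if (is.null(outdir)) return(NULL)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, name)
    writer(path)
    path
  }
  files <- character(0)

  # --- stage hqc ---------------------------------------------------------
  hqc_A <- run_hqc(data$geno_A, data$intens_A, data$ann_A,
                   het_level = config$het_level, bin_width = config$bin_width,
                   threshold = config$threshold_A,
                   marker_min = config$marker_min)
  hqc_B <- run_hqc(data$geno_B, data$intens_B, data$ann_B,
                   het_level = config$het_level, bin_width = config$bin_width,
                   threshold = config$threshold_B,
                   marker_min = config$marker_min)
  samples <- intersect(names(hqc_A$sample_rates), names(hqc_B$sample_rates))
  rates <- cbind(A = hqc_A$sample_rates[samples], B = hqc_B$sample_rates[samples])
  keep <- rownames(rates)[apply(rates > config$sample_min, 1, all)]
  if (!length(keep)) stop("stage hqc: all samples removed")
  gA <- genotype_matrix(unclass(hqc_A$genotypes)[keep, , drop = FALSE])
  gB <- genotype_matrix(unclass(hqc_B$genotypes)[keep, , drop = FALSE])
  iA <- intensity_matrix(unclass(data$intens_A)[keep, , drop = FALSE])
  iB <- intensity_matrix(unclass(data$intens_B)[keep, , drop = FALSE])
  files <- c(files,
             emit("hqc_genotypes_A.tsv", function(p) write_matrix(gA, p)),
             emit("hqc_genotypes_B.tsv", function(p) write_matrix(gB, p)))

  # --- stage merge -------------------------------------------------------
  rec <- reconcile_strands(data$ann_A, data$ann_B, gA, gB,
                           freq_tolerance = config$freq_tolerance,
                           rare_maf = config$rare_maf)
  mg <- merge_calls(gA, gB, rec, data$ann_A)
  files <- c(files,
             emit("merged_genotypes.tsv", function(p) write_matrix(mg$genotypes, p)),
             emit("flip_set.tsv", function(p) {
               utils::write.table(data.frame(marker_id = rec$flip_set), p,
                                  sep = "\t", quote = FALSE, row.names = FALSE)
             }))

  # --- stage ldbin -------------------------------------------------------
  bins <- ld_bins(mg$genotypes, mg$annotation, maf_min = config$maf_min,
                  window_bp = config$window_bp,
                  r2_threshold = config$r2_threshold)
  files <- c(files, emit("ld_bins.tsv", function(p) {
    flat <- dplyr::mutate(bins,
                          members = vapply(.data$members, paste,
                                           character(1), collapse = ","))
    utils::write.table(flat, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }))

  # --- stage segment -----------------------------------------------------
  run_seg <- function(intens, ann, platform, fixed_loss) {
    seg <- segment_platform(intens, ann, platform = platform,
                            alpha = config$alpha, n_perm = config$n_perm,
                            min_width = config$min_width,
                            master_seed = config$master_seed)
    seg <- split_at_centromere(seg, data$genome, intens, ann)
    prof <- coverage_profile(seg, bin_width = config$bin_width)
    loss_thr <- if (is.null(fixed_loss)) find_loss_threshold(prof) else fixed_loss
    cnv <- classify_and_filter(seg, loss_thr,
                               gain_threshold = config$gain_threshold,
                               min_size_bp = config$min_size_bp)
    list(segments = seg, profile = prof, loss_threshold = loss_thr, cnv = cnv)
  }
  seg_A <- run_seg(iA, data$ann_A, "A", config$loss_threshold_A)
  seg_B <- run_seg(iB, data$ann_B, "B", config$loss_threshold_B)
  files <- c(files,
             emit("cnv_segments_A.bed", function(p) {
               write_bed(dplyr::mutate(seg_A$cnv, name = .data$state,
                                       score = round(100 * .data$mean_intensity)), p)
             }),
             emit("cnv_segments_B.bed", function(p) {
               write_bed(dplyr::mutate(seg_B$cnv, name = .data$state,
                                       score = round(100 * .data$mean_intensity)), p)
             }))

  # --- stage regions -----------------------------------------------------
  conc <- intersect_platforms(seg_A$cnv, seg_B$cnv,
                              min_overlap_bp = config$min_overlap_bp)
  szc <- if (nrow(conc$pairs)) {
    suppressWarnings(size_correlation(conc, config$size_corr_min_bp))
  } else {
    tibble::tibble(estimate = NA_real_, n_pairs = 0L)
  }
  all_cnv <- dplyr::bind_rows(seg_A$cnv, seg_B$cnv)
  reg <- merge_to_regions(all_cnv, data$genome,
                          merge_bookended = config$merge_bookended)
  files <- c(files, emit("cnv_regions.bed", function(p) {
    write_bed(dplyr::mutate(reg$regions, name = "CNVR",
                            score = .data$n_contributing,
                            contributing = NULL), p)
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("haplocnv")),
    parameters = unclass(config),
    counts = list(
      samples_in = nrow(data$geno_A), samples_retained = length(keep),
      markers_A_post_qc = ncol(gA), markers_B_post_qc = ncol(gB),
      merged_markers = ncol(mg$genotypes),
      shared_snps = mg$report$n_shared_snps,
      flipped = mg$report$n_flipped,
      discordant = mg$report$n_discordant_forced,
      ld_bins = nrow(bins),
      singleton_bins = sum(bins$n_members == 1),
      cnv_segments_A = nrow(seg_A$cnv), cnv_segments_B = nrow(seg_B$cnv),
      cnv_regions = nrow(reg$regions)
    ),
    checksums = if (length(files)) as.list(tools::md5sum(files)) else list()
  )
  structure(list(
    hqc_A = hqc_A, hqc_B = hqc_B, samples_retained = keep,
    merge = mg, reconciliation = rec, bins = bins,
    segments_A = seg_A, segments_B = seg_B,
    cnv_segments = all_cnv, concordance = conc, size_correlation = szc,
    regions = reg$regions, genome_fraction = reg$genome_fraction,
    manifest = manifest
  ), class = "chm_pipeline_result")
}

#' @export
print.chm_pipeline_result <- function(x, ...) {
  ct <- x$manifest$counts
  cat("<chm_pipeline_result>\n",
      "  samples retained: ", ct$samples_retained, "/", ct$samples_in, "\n",
      "  merged markers:   ", ct$merged_markers, " (", ct$shared_snps,
      " shared SNPs, ", ct$flipped, " flipped, ", ct$discordant,
      " discordant)\n",
      "  LD bins:          ", ct$ld_bins, " (", ct$singleton_bins,
      " singletons)\n",
      "  CNV segments:     A ", ct$cnv_segments_A, ", B ",
      ct$cnv_segments_B, "\n",
      "  CNV regions:      ", ct$cnv_regions, " (",
      sprintf("%.2f%%", 100 * x$genome_fraction), " of genome)\n", sep = "")
  invisible(x)
}

#' @export
glance.chm_pipeline_result <- function(x, ...) {
  ct <- x$manifest$counts
  tibble::tibble(
    samples_retained = ct$samples_retained,
    merged_markers = ct$merged_markers,
    discordance_fraction = x$merge$report$discordance_fraction,
    n_ld_bins = ct$ld_bins,
    n_singleton_bins = ct$singleton_bins,
    loss_threshold_A = x$segments_A$loss_threshold,
    loss_threshold_B = x$segments_B$loss_threshold,
    n_cnv_segments_A = ct$cnv_segments_A,
    n_cnv_segments_B = ct$cnv_segments_B,
    n_cnv_regions = ct$cnv_regions,
    genome_fraction = x$genome_fraction
  )
}
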