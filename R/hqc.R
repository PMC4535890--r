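# Haploid quality control (HQC).  A duplicated haploid genome is expected
# to be homozygous everywhere, so heterozygous calls are artifacts, and
# their enrichment at low relative signal intensity marks deleted (or
# divergent paralogous) regions where calls are unreliable.  HQC derives an
# intensity reliability threshold from the het-vs-intensity curve, forces
# het and weak-signal calls to no-calls, then removes duplicate-position
# markers, low-call-rate markers and low-call-rate samples.

align_calls_intensity <- function(genotypes, intensities) {
  common <- intersect(colnames(genotypes), colnames(intensities))
  if (!length(common)) stop("genotype and intensity matrices share no markers")
  if (!identical(rownames(genotypes), rownames(intensities))) {
    stop("genotype and intensity matrices must have identical sample sets")
  }
  list(g = unclass(genotypes)[, common, drop = FALSE],
       x = unclass(intensities)[, common, drop = FALSE])
}

#' Heterozygosity as a function of relative signal intensity
#'
#' Bins every called genotype (anything but `NC`) by the marker's relative
#' signal intensity in that sample and reports the heterozygous fraction
#' per bin, plus the cumulative fraction of all calls lying below each
#' bin's upper edge.  Bins are `[lower, lower + bin_width)` anchored at
#' integer multiples of `bin_width`; bins with no calls have an undefined
#' (`NaN`) het fraction.
#'
#' @param genotypes A [genotype_matrix()].
#' @param intensities The paired [intensity_matrix()] (markers are matched
#'   by id; calls without an intensity value are ignored).
#' @param bin_width Intensity bin width, default 0.1.
#' @return A `het_intensity_curve` tibble with columns `bin_lower`,
#'   `bin_upper`, `n_calls`, `n_het`, `het_fraction`, `frac_calls_below`
#'   (fraction of all calls strictly below `bin_upper`).
#' @export
het_intensity_curve <- function(genotypes, intensities, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  al <- align_calls_intensity(genotypes, intensities)
  called <- al$g != "NC" & !is.na(al$x)
  if (!any(called)) stop("no called genotypes with intensity values")
  x <- al$x[called]
  het <- al$g[called] == "AB"
  lo <- floor(x / bin_width + 1e-9) * bin_width
  edges <- seq(min(lo), max(lo), by = bin_width)
  idx <- round((lo - edges[1]) / bin_width) + 1L
  n_calls <- tabulate(idx, nbins = length(edges))
  n_het <- tabulate(idx[het], nbins = length(edges))
  curve <- tibble::tibble(
    bin_lower = edges,
    bin_upper = edges + bin_width,
    n_calls = n_calls,
    n_het = n_het,
    het_fraction = n_het / n_calls,
    frac_calls_below = cumsum(n_calls) / sum(n_calls)
  )
  class(curve) <- c("het_intensity_curve", class(curve))
  attr(curve, "bin_width") <- bin_width
  curve
}

#' Derive the intensity reliability threshold from the het curve
#'
#' Scanning bins from low to high intensity, the threshold is the upper
#' edge of the highest-intensity bin whose het fraction is at or above
#' `het_level` (default 1\%): all calls strictly below that edge are deemed
#' unreliable.  Bins without calls are skipped.  If no bin reaches
#' `het_level` the `-Inf` sentinel is returned (nothing will be forced);
#' if every populated bin reaches it the data are unusable and an error is
#' raised.
#'
#' @param curve A [het_intensity_curve()].
#' @param het_level Heterozygosity level marking unreliable calls.
#' @return The intensity threshold (possibly `-Inf`).
#' @export
find_intensity_threshold <- function(curve, het_level = 0.01) {
  defined <- curve$n_calls > 0
  hot <- defined & curve$het_fraction >= het_level
  if (all(hot[defined])) {
    stop("het fraction >= ", het_level, " in every populated bin; data unusable")
  }
  if (!any(hot)) return(-Inf)
  curve$bin_upper[max(which(hot))]
}

#' Force heterozygous and weak-signal calls to no-calls
#'
#' Every heterozygous call becomes a no-call regardless of intensity, and
#' every call with intensity strictly below `threshold` becomes a no-call.
#' A het below the threshold is tallied once, as a low-intensity forcing.
#' Calls whose intensity is missing are only subject to the het rule.
#'
#' @inheritParams het_intensity_curve
#' @param threshold Intensity cutoff; `-Inf` disables intensity forcing.
#' @return List with `genotypes` (forced matrix) and `report` (an
#'   `hqc_report` with forcing tallies).
#' @export
apply_hqc <- function(genotypes, intensities, threshold) {
  al <- align_calls_intensity(genotypes, intensities)
  g <- unclass(genotypes)
  called <- al$g != "NC"
  low <- called & !is.na(al$x) & al$x < threshold
  het_only <- called & al$g == "AB" & !low
  gc2 <- al$g
  gc2[low | het_only] <- "NC"
  g[, colnames(gc2)] <- gc2
  # hets on markers without intensity data still violate haploidy
  no_x <- setdiff(colnames(g), colnames(gc2))
  n_het_extra <- 0L
  if (length(no_x)) {
    sub <- g[, no_x, drop = FALSE]
    n_het_extra <- sum(sub == "AB")
    sub[sub == "AB"] <- "NC"
    g[, no_x] <- sub
  }
  n_calls <- sum(unclass(genotypes) != "NC")
  report <- structure(list(
    threshold = threshold,
    n_low_intensity_forced = sum(low),
    n_het_forced = sum(het_only) + n_het_extra,
    fraction_forced = (sum(low) + sum(het_only) + n_het_extra) / n_calls
  ), class = "hqc_report")
  list(genotypes = genotype_matrix(g), report = report)
}

#' @export
print.hqc_report <- function(x, ...) {
  cat("<hqc_report> threshold ", x$threshold, "; ", x$n_het_forced,
      " het + ", x$n_low_intensity_forced, " low-intensity calls forced (",
      sprintf("%.3f%%", 100 * x$fraction_forced), " of calls)\n", sep = "")
  invisible(x)
}

#' @export
glance.hqc_report <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_het_forced = x$n_het_forced,
                 n_low_intensity_forced = x$n_low_intensity_forced,
                 fraction_forced = x$fraction_forced)
}

#' Remove all markers sharing a genome position
#'
#' Arrays occasionally carry two (or more) probes at one `(chrom, pos)`;
#' with no principled tie-break, every member of such a group is removed.
#'
#' @param annotation Marker annotation for the platform.
#' @param genotypes A [genotype_matrix()] whose markers are a subset of the
#'   annotation.
#' @return List with `genotypes` (duplicates dropped) and `removed_ids`.
#' @export
remove_duplicate_position_markers <- function(annotation, genotypes) {
  ann <- annotation[annotation$marker_id %in% colnames(genotypes), ]
  key <- paste(ann$chrom, ann$pos)
  dup_key <- key %in% key[duplicated(key)]
  removed <- ann$marker_id[dup_key]
  keep <- setdiff(colnames(genotypes), removed)
  list(genotypes = genotype_matrix(unclass(genotypes)[, keep, drop = FALSE]),
       removed_ids = removed)
}

#' Filter markers and samples by call rate
#'
#' Markers with call rate below `marker_min` are removed (exactly
#' `marker_min` is retained).  Samples are retained only when their call
#' rate is strictly above `sample_min` on every platform: pass
#' `per_platform_sample_rates` (samples x platforms matrix of rates
#' computed after HQC forcing on each platform) for the joint rule; if
#' omitted, this matrix's own sample rates are used.
#'
#' @param genotypes A [genotype_matrix()].
#' @param marker_min Minimum marker call rate (kept when `>=`), default 0.90.
#' @param sample_min Sample call-rate bound (kept when strictly `>`),
#'   default 0.96.
#' @param per_platform_sample_rates Optional numeric matrix, rownames =
#'   sample ids, one column per platform.
#' @return List with `genotypes` and `report` (tibble of removed counts).
#' @export
filter_by_call_rate <- function(genotypes, marker_min = 0.90,
                                sample_min = 0.96,
                                per_platform_sample_rates = NULL) {
  g <- unclass(genotypes)
  marker_rate <- colMeans(g != "NC")
  g <- g[, marker_rate >= marker_min, drop = FALSE]
  if (is.null(per_platform_sample_rates)) {
    per_platform_sample_rates <- cbind(rowMeans(unclass(genotypes) != "NC"))
    rownames(per_platform_sample_rates) <- rownames(g)
  }
  rates <- per_platform_sample_rates[rownames(g), , drop = FALSE]
  keep_sample <- apply(rates > sample_min, 1, all)
  if (!any(keep_sample)) stop("all samples removed by the call-rate filter")
  g <- g[keep_sample, , drop = FALSE]
  list(
    genotypes = genotype_matrix(g),
    report = tibble::tibble(
      n_markers_removed_call_rate = sum(marker_rate < marker_min),
      n_samples_removed = sum(!keep_sample),
      samples_retained = sum(keep_sample)
    )
  )
}

#' Run the full haploid-QC stage for one platform
#'
#' Computes the het-intensity curve, derives (or takes) the intensity
#' threshold, forces het and weak-signal calls to no-calls, and removes
#' duplicate-position markers and low-call-rate markers.  The joint
#' both-platform sample filter is applied afterwards by the pipeline via
#' [filter_by_call_rate()].
#'
#' @inheritParams het_intensity_curve
#' @param annotation The platform's marker annotation.
#' @param het_level Het level for threshold derivation.
#' @param threshold Fixed threshold override (e.g. -0.6 for a log2R
#'   platform, -1 for a logRR platform); `NULL` derives it from the curve.
#' @param marker_min Minimum marker call rate.
#' @return List with `genotypes`, `curve`, `threshold`, `hqc_report`,
#'   `removed_duplicate_ids`, `marker_report` and `sample_rates` (post-HQC
#'   per-sample call rates, for the joint filter).
#' @export
run_hqc <- function(genotypes, intensities, annotation, het_level = 0.01,
                    bin_width = 0.1, threshold = NULL, marker_min = 0.90) {
  curve <- het_intensity_curve(genotypes, intensities, bin_width)
  if (is.null(threshold)) threshold <- find_intensity_threshold(curve, het_level)
  forced <- apply_hqc(genotypes, intensities, threshold)
  dedup <- remove_duplicate_position_markers(annotation, forced$genotypes)
  g <- unclass(dedup$genotypes)
  marker_rate <- colMeans(g != "NC")
  g2 <- g[, marker_rate >= marker_min, drop = FALSE]
  list(
    genotypes = genotype_matrix(g2),
    curve = curve,
    threshold = threshold,
    hqc_report = forced$report,
    removed_duplicate_ids = dedup$removed_ids,
    n_markers_removed_call_rate = sum(marker_rate < marker_min),
    sample_rates = rowMeans(g2 != "NC")
  )
}
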