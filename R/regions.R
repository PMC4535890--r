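# Cross-platform segment concordance and CNV-region synthesis.  Interval
# arithmetic is on 1-based closed intervals (overlap length =
# min(endA, endB) - max(startA, startB) + 1); the union/reduce step is
# delegated to GenomicRanges.

#' Cross-platform CNV-segment concordance
#'
#' For each sample, a platform-A CNV segment is counted as overlapping
#' when at least `min_overlap_bp` of it intersects any platform-B CNV
#' segment of the same sample, and vice versa.  Overlaps between a gain on
#' one platform and a loss on the other are tallied separately.
#'
#' @param segments_A,segments_B Classified CNV-segment tibbles (columns
#'   `sample_id`, `chrom`, `start`, `end`, `state`) from the same sample
#'   set.
#' @param min_overlap_bp Minimal overlap, default 1 bp.
#' @return A `concordance_report`: counts plus a `pairs` tibble with both
#'   segments' coordinates, lengths, states and the overlap length.
#' @export
intersect_platforms <- function(segments_A, segments_B, min_overlap_bp = 1) {
  a <- dplyr::mutate(tibble::as_tibble(segments_A),
                     id_A = dplyr::row_number(),
                     len_A = .data$end - .data$start + 1)
  b <- dplyr::mutate(tibble::as_tibble(segments_B),
                     id_B = dplyr::row_number(),
                     len_B = .data$end - .data$start + 1)
  pairs <- dplyr::inner_join(
    dplyr::select(a, "id_A", "sample_id", "chrom", start_A = "start",
                  end_A = "end", state_A = "state", "len_A"),
    dplyr::select(b, "id_B", "sample_id", "chrom", start_B = "start",
                  end_B = "end", state_B = "state", "len_B"),
    by = c("sample_id", "chrom"), relationship = "many-to-many"
  )
  pairs$overlap_bp <- pmin(pairs$end_A, pairs$end_B) -
    pmax(pairs$start_A, pairs$start_B) + 1
  pairs <- pairs[pairs$overlap_bp >= min_overlap_bp, , drop = FALSE]
  pairs$opposite_state <- pairs$state_A != pairs$state_B
  structure(list(
    n_segments_A = nrow(a), n_segments_B = nrow(b),
    n_overlapping_A = length(unique(pairs$id_A)),
    n_overlapping_B = length(unique(pairs$id_B)),
    n_opposite_state_overlaps = sum(pairs$opposite_state),
    min_overlap_bp = min_overlap_bp,
    pairs = tibble::as_tibble(pairs)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> A: ", x$n_overlapping_A, "/", x$n_segments_A,
      " overlapped; B: ", x$n_overlapping_B, "/", x$n_segments_B,
      "; opposite-state overlaps: ", x$n_opposite_state_overlaps, "\n",
      sep = "")
  invisible(x)
}

#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(
    n_segments_A = x$n_segments_A, n_segments_B = x$n_segments_B,
    n_overlapping_A = x$n_overlapping_A, n_overlapping_B = x$n_overlapping_B,
    fraction_overlapping_A = x$n_overlapping_A / max(x$n_segments_A, 1L),
    fraction_overlapping_B = x$n_overlapping_B / max(x$n_segments_B, 1L),
    n_opposite_state_overlaps = x$n_opposite_state_overlaps
  )
}

#' @export
tidy.concordance_report <- function(x, ...) x$pairs

#' Size correlation of overlapped segments
#'
#' Pearson correlation of log10 segment lengths over overlapped pairs
#' where both segments are strictly longer than `min_length_bp`.
#'
#' @param report A [intersect_platforms()] result.
#' @param min_length_bp Length cut, default 10000 (10 kb).
#' @return One-row tibble with `estimate` (`NA` with a warning when fewer
#'   than 3 qualifying pairs exist) and `n_pairs`.
#' @export
size_correlation <- function(report, min_length_bp = 10000) {
  p <- report$pairs
  p <- p[p$len_A > min_length_bp & p$len_B > min_length_bp, , drop = FALSE]
  if (nrow(p) < 3) {
    warning("fewer than 3 qualifying pairs; size correlation undefined")
    return(tibble::tibble(estimate = NA_real_, n_pairs = nrow(p)))
  }
  tibble::tibble(
    estimate = stats::cor(log10(p$len_A), log10(p$len_B)),
    n_pairs = nrow(p)
  )
}

#' Merge CNV segments into CNV regions
#'
#' Takes the union of all CNV segments across samples and platforms,
#' ignoring state: overlapping — and, by default, bookended (adjacent-bp)
#' — intervals merge into one region.  The genome fraction is the total
#' region length over the total genome length from the metadata.
#'
#' @param segments Combined classified CNV-segment tibble (both
#'   platforms, loss/gain only).
#' @param genome_metadata Genome metadata tibble.
#' @param merge_bookended Merge intervals whose ends are adjacent
#'   (`end + 1 == next start`), default `TRUE`.
#' @return List with `regions` (tibble `chrom`, `start`, `end`,
#'   `n_contributing`, `contributing` list column of
#'   sample/platform/state rows) and `genome_fraction`.
#' @export
merge_to_regions <- function(segments, genome_metadata,
                             merge_bookended = TRUE) {
  seg <- tibble::as_tibble(segments)
  lens <- stats::setNames(genome_metadata$length_bp, genome_metadata$chrom)
  bad <- !seg$chrom %in% names(lens) | seg$end > lens[seg$chrom]
  if (any(bad)) {
    stop("segment beyond chromosome end: ", seg$chrom[bad][1], ":",
         seg$start[bad][1], "-", seg$end[bad][1])
  }
  if (!nrow(seg)) {
    return(list(regions = tibble::tibble(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         n_contributing = integer(0),
                                         contributing = list()),
                genome_fraction = 0))
  }
  gr <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = if (merge_bookended) 1L else 0L)
  hits <- GenomicRanges::findOverlaps(red, gr)
  contrib_cols <- intersect(c("sample_id", "platform", "state"), names(seg))
  contributing <- lapply(seq_along(red), function(i) {
    seg[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i],
        contrib_cols, drop = FALSE]
  })
  regions <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    n_contributing = vapply(contributing, nrow, integer(1)),
    contributing = contributing
  )
  regions <- regions[order(chrom_rank(regions$chrom), regions$start), ]
  list(regions = regions,
       genome_fraction = sum(regions$end - regions$start + 1) /
         sum(genome_metadata$length_bp))
}
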