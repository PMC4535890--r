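# Circular binary segmentation (CBS) of per-sample relative-intensity
# profiles, with a permutation test for split acceptance, centromere
# splitting, the segment-coverage distribution over mean-intensity bins,
# data-derived loss thresholds, and segment classification/filtering.

#' Best circular split of an intensity vector
#'
#' Maximizes, over arc boundaries `(i, j)`, the absolute two-sample t-like
#' statistic comparing the arc mean with the complement mean (both parts
#' at least `min_width` markers).  `i = 0` or `j = n` reduce to an
#' ordinary single change point.
#'
#' @param values Numeric vector (no missing values).
#' @param min_width Minimum markers in either part, default 2.
#' @return List with `i`, `j` (the arc is `values[(i+1):j]`) and `stat`;
#'   `stat = 0` with `NA` boundaries when no split exists (constant or too
#'   short input).
#' @export
cbs_max_split <- function(values, min_width = 2) {
  .cbs_max_arc(as.numeric(values), as.integer(min_width))
}

#' Segment one ordered intensity profile by CBS
#'
#' Recursively applies [cbs_max_split()]; a candidate split is accepted
#' when its permutation p-value (share of `n_perm` random permutations of
#' the current segment's values whose best-split statistic reaches the
#' observed one) is at most `alpha`.  Missing values are dropped before
#' segmentation.  Segment coordinates span the first to last contributing
#' marker.
#'
#' @param values Intensities of one sample/platform/chromosome, in marker
#'   order (`NA` allowed).
#' @param positions Matching 1-based bp positions.
#' @param alpha Split acceptance level, default 0.01.
#' @param n_perm Number of permutations, default 10000.
#' @param min_width Minimum markers per segment part, default 2.
#' @param seed Optional RNG seed for the permutation test.
#' @return Tibble with one row per segment: `start`, `end` (bp, marker
#'   span), `n_markers`, `mean_intensity`, plus `first_idx`/`last_idx`
#'   (indices into the non-missing marker sequence).
#' @export
cbs_segment <- function(values, positions, alpha = 0.01, n_perm = 10000,
                        min_width = 2, seed = NULL) {
  keep <- !is.na(values)
  if (!any(keep)) stop("no non-missing values to segment")
  x <- as.numeric(values[keep])
  pos <- positions[keep]
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  early_limit <- floor(alpha * n_perm)

  boundaries <- integer(0)  # last index of each closed segment piece
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_width) return(invisible(NULL))
    sp <- .cbs_max_arc(x[lo:hi], as.integer(min_width))
    if (!is.finite(sp$stat) || sp$stat <= 0 || is.na(sp$i)) return(invisible(NULL))
    pc <- .cbs_perm_count(x[lo:hi], sp$stat, as.integer(n_perm),
                          as.integer(min_width), as.integer(early_limit))
    if (pc$count > early_limit || pc$count / n_perm > alpha) return(invisible(NULL))
    i <- sp$i; j <- sp$j
    cuts <- integer(0)
    if (i > 0) cuts <- c(cuts, lo + i - 1L)
    if (j < len) cuts <- c(cuts, lo + j - 1L)
    boundaries <<- c(boundaries, cuts)
    pieces_lo <- c(lo, cuts + 1L)
    pieces_hi <- c(cuts, hi)
    for (k in seq_along(pieces_lo)) recurse(pieces_lo[k], pieces_hi[k])
    invisible(NULL)
  }
  recurse(1L, n)
  ends <- sort(unique(c(boundaries, n)))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tibble::tibble(
    start = pos[starts], end = pos[ends],
    n_markers = ends - starts + 1L,
    mean_intensity = vapply(seq_along(starts), function(k) {
      mean(x[starts[k]:ends[k]])
    }, numeric(1)),
    first_idx = starts, last_idx = ends
  )
}

# stable 32-bit string hash for per-(sample, chrom) permutation seeds
stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Segment every sample and chromosome of one platform
#'
#' Runs [cbs_segment()] per sample and chromosome; the permutation RNG is
#' seeded per `(platform, sample, chrom)` by a stable string hash combined
#' with `master_seed`, so results do not depend on execution order.
#'
#' @param intensities An [intensity_matrix()].
#' @param annotation The platform's marker annotation (all probe classes
#'   contribute intensity).
#' @param platform Platform label stored in the output.
#' @inheritParams cbs_segment
#' @param master_seed Master seed for the per-profile permutation seeds.
#' @return Segment tibble with columns `sample_id`, `platform`, `chrom`,
#'   `start`, `end`, `n_markers`, `mean_intensity`.
#' @export
segment_platform <- function(intensities, annotation, platform = "A",
                             alpha = 0.01, n_perm = 10000, min_width = 2,
                             master_seed = 1) {
  ann <- annotation[annotation$marker_id %in% colnames(intensities), ]
  x <- unclass(intensities)
  purrr::map_dfr(split(ann, ann$chrom), function(ac) {
    ac <- ac[order(ac$pos, ac$marker_id), ]
    purrr::map_dfr(rownames(x), function(s) {
      v <- x[s, ac$marker_id]
      if (all(is.na(v))) return(tibble::tibble())
      seed <- (master_seed + stable_hash(paste(platform, s, ac$chrom[1]))) %%
        2147483647
      seg <- cbs_segment(v, ac$pos, alpha = alpha, n_perm = n_perm,
                         min_width = min_width, seed = seed)
      tibble::tibble(sample_id = s, platform = platform, chrom = ac$chrom[1],
                     start = seg$start, end = seg$end,
                     n_markers = seg$n_markers,
                     mean_intensity = seg$mean_intensity)
    })
  })
}

#' Split segments extending beyond a centromere
#'
#' A segment overlapping a centromere interval is clipped into a p-arm
#' part ending at `centromere_start - 1` and a q-arm part starting at
#' `centromere_end + 1`.  When the marker data are supplied, each part's
#' marker count and mean intensity are recomputed and its coordinates
#' re-snapped to the span of its remaining markers; parts with no markers
#' are dropped.
#'
#' @param segments Segment tibble (see [segment_platform()]).
#' @param genome_metadata Genome metadata tibble with centromere intervals.
#' @param intensities,annotation Optional marker data for recomputation.
#' @return The split segment tibble.
#' @export
split_at_centromere <- function(segments, genome_metadata,
                                intensities = NULL, annotation = NULL) {
  gm <- genome_metadata
  cen_s <- stats::setNames(gm$centromere_start, gm$chrom)
  cen_e <- stats::setNames(gm$centromere_end, gm$chrom)
  rows <- purrr::map_dfr(seq_len(nrow(segments)), function(k) {
    sg <- segments[k, ]
    if (!sg$chrom %in% names(cen_s)) return(sg)
    cs <- cen_s[[sg$chrom]]; ce <- cen_e[[sg$chrom]]
    if (sg$end < cs || sg$start > ce) return(sg)
    parts <- tibble::tibble(start = integer(0), end = integer(0))
    if (sg$start <= cs - 1) parts <- dplyr::add_row(parts, start = sg$start, end = cs - 1L)
    if (sg$end >= ce + 1) parts <- dplyr::add_row(parts, start = ce + 1L, end = sg$end)
    if (!nrow(parts)) return(parts[0, ])
    out <- sg[rep(1, nrow(parts)), ]
    out$start <- as.integer(parts$start); out$end <- as.integer(parts$end)
    if (!is.null(intensities) && !is.null(annotation)) {
      out <- purrr::map_dfr(seq_len(nrow(out)), function(p) {
        part <- out[p, ]
        ann <- annotation[annotation$chrom == part$chrom &
                          annotation$pos >= part$start &
                          annotation$pos <= part$end &
                          annotation$marker_id %in% colnames(intensities), ]
        v <- unclass(intensities)[part$sample_id, ann$marker_id]
        ok <- !is.na(v)
        if (!any(ok)) return(part[0, ])
        part$start <- min(ann$pos[ok]); part$end <- max(ann$pos[ok])
        part$n_markers <- sum(ok)
        part$mean_intensity <- mean(v[ok])
        part
      })
    }
    out
  })
  rows
}

#' Segment coverage by mean-intensity bin
#'
#' Accumulates each segment's bp length into the bin of its mean
#' intensity (bins `[lower, lower + bin_width)` anchored at multiples of
#' `bin_width`, empty bins kept) and the cumulative coverage from the most
#' negative bin upward.
#'
#' @param segments Segment tibble.
#' @param bin_width Intensity bin width, default 0.1.
#' @return A `segment_coverage_profile` tibble with `bin_lower`,
#'   `bin_upper`, `bp_covered`, `cumulative_bp`.
#' @export
coverage_profile <- function(segments, bin_width = 0.1) {
  stopifnot(nrow(segments) > 0)
  lo <- floor(segments$mean_intensity / bin_width + 1e-9) * bin_width
  len <- segments$end - segments$start + 1
  edges <- seq(min(lo), max(lo), by = bin_width)
  idx <- round((lo - edges[1]) / bin_width) + 1L
  bp <- vapply(seq_along(edges), function(i) sum(len[idx == i]), numeric(1))
  prof <- tibble::tibble(
    bin_lower = edges, bin_upper = edges + bin_width,
    bp_covered = bp, cumulative_bp = cumsum(bp)
  )
  class(prof) <- c("segment_coverage_profile", class(prof))
  attr(prof, "bin_width") <- bin_width
  prof
}

#' Data-derived loss threshold from the coverage profile
#'
#' The deletion peak and the main (near-zero) peak of the segment-coverage
#' distribution are separated by a coverage minimum — the plateau of the
#' cumulative coverage curve.  The threshold returned is the upper edge of
#' the minimum-coverage bin strictly between the lowest-intensity mode and
#' the main mode (ties resolved at the middle of the minimal run).  With
#' no covered bin below zero, the `-Inf` sentinel is returned (no losses).
#'
#' @param profile A [coverage_profile()].
#' @return The loss threshold (possibly `-Inf`).
#' @export
find_loss_threshold <- function(profile) {
  bp <- profile$bp_covered
  if (!any(bp > 0)) stop("empty coverage profile")
  main_idx <- which.max(bp)
  if (!any(bp > 0 & profile$bin_upper <= 1e-9)) return(-Inf)
  # the deletion peak is the mode of the lowest-intensity contiguous run of
  # covered bins; it must be separated from the run holding the main mode
  covered <- bp > 0
  run_id <- cumsum(c(TRUE, diff(covered) != 0))
  first_run <- which(covered & run_id == run_id[which(covered)[1]])
  if (main_idx %in% first_run) {
    if (profile$bin_upper[main_idx] <= 1e-9) {
      stop("cannot bracket a loss threshold: no coverage mode near zero")
    }
    return(-Inf)   # unimodal profile, nothing below detaches as a loss mode
  }
  loss_idx <- first_run[which.max(bp[first_run])]
  between <- seq_along(bp)
  between <- between[between > loss_idx & between < main_idx]
  if (!length(between)) {
    stop("cannot bracket a loss threshold between the loss and main modes")
  }
  mn <- min(bp[between])
  run <- between[bp[between] == mn]
  pick <- run[ceiling(length(run) / 2)]
  profile$bin_upper[pick]
}

#' Classify segments and filter by size
#'
#' A segment is a loss when its mean intensity is strictly below
#' `loss_threshold`, a gain when strictly above `gain_threshold`, neutral
#' otherwise.  Segments of every state with length `<= min_size_bp` are
#' then removed, and only loss/gain segments are returned as CNV segments
#' unless `keep_neutral = TRUE`.
#'
#' @param segments Segment tibble.
#' @param loss_threshold Loss boundary (e.g. -1 for log2R, -2 for logRR,
#'   or the value derived by [find_loss_threshold()]).
#' @param gain_threshold Gain boundary, default 0.5.
#' @param min_size_bp Minimum segment length; only lengths strictly
#'   greater are kept.  Default 50.
#' @param keep_neutral Keep neutral segments in the output (for coverage
#'   accounting), default `FALSE`.
#' @return The classified segment tibble with a `state` column.
#' @export
classify_and_filter <- function(segments, loss_threshold,
                                gain_threshold = 0.5, min_size_bp = 50,
                                keep_neutral = FALSE) {
  if (loss_threshold >= gain_threshold) {
    stop("loss_threshold must be below gain_threshold")
  }
  out <- dplyr::mutate(
    segments,
    state = dplyr::case_when(
      .data$mean_intensity < loss_threshold ~ "loss",
      .data$mean_intensity > gain_threshold ~ "gain",
      TRUE ~ "neutral"
    )
  )
  out <- out[(out$end - out$start + 1) > min_size_bp, , drop = FALSE]
  if (!keep_neutral) out <- out[out$state != "neutral", , drop = FALSE]
  out
}
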