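# Haploid linkage disequilibrium, LD bins and tagSNPs.  Calls from a
# duplicated haploid genome are directly phased haplotypes, so pairwise r2
# is computed from joint haplotype frequencies:  with p = freq(allele a at
# marker i), q = freq(allele a at j) and f = joint freq(a, a),
# D = f - p*q and r2 = D^2 / (p(1-p) q(1-q)).  Common SNPs are grouped by
# a greedy maximal binning at r2 >= 0.80 (ldSelect-style), and each bin's
# tagSNP is the member with maximal average r2 to the rest ("avesnp").

#' Pairwise haploid r2 among common SNPs
#'
#' Computes r2 for every same-chromosome pair of common SNPs at most
#' `window_bp` apart, from the samples called at both markers.  A marker's
#' minor-allele frequency is computed over its non-missing calls; markers
#' below `maf_min` are dropped before pairing, and pairs monomorphic among
#' their jointly called samples are skipped.
#'
#' @param genotypes Merged haploid [genotype_matrix()] (no het calls).
#' @param annotation Matching marker annotation (positions).
#' @param maf_min Minimum minor-allele frequency, default 0.05.
#' @param window_bp Maximum inter-marker distance, default 300000.
#' @return A tibble with columns `marker_i`, `marker_j`, `chrom`,
#'   `distance_bp`, `r2` (markers ordered by position within a pair), and
#'   the set of common SNPs as attribute `"common_snps"`.
#' @export
pairwise_r2 <- function(genotypes, annotation, maf_min = 0.05,
                        window_bp = 300000) {
  g <- unclass(genotypes)
  ann <- annotation[annotation$probe_class == "snp" &
                    annotation$marker_id %in% colnames(g), ]
  x <- matrix(NA_real_, nrow = nrow(g), ncol = nrow(ann),
              dimnames = list(rownames(g), ann$marker_id))
  sub <- g[, ann$marker_id, drop = FALSE]
  x[sub == "AA"] <- 1
  x[sub == "BB"] <- 0
  called_n <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / pmax(called_n, 1L)
  maf <- pmin(p, 1 - p)
  common <- called_n > 0 & maf >= maf_min
  ann <- ann[common, ]
  x <- x[, common, drop = FALSE]

  out <- purrr::map_dfr(split(seq_len(nrow(ann)), ann$chrom), function(ix) {
    if (length(ix) < 2) return(tibble::tibble())
    xa <- x[, ix, drop = FALSE]
    pos <- ann$pos[ix]
    called <- !is.na(xa)
    x0 <- xa; x0[!called] <- 0
    n_joint <- crossprod(called)               # samples called at both
    n_aa <- crossprod(x0)                      # joint allele-a count
    n_a_i <- crossprod(x0, called)             # allele-a at i among joint
    pj <- n_a_i / n_joint                      # row marker's freq in pair
    f <- n_aa / n_joint
    D <- f - pj * t(pj)
    den <- pj * (1 - pj) * t(pj * (1 - pj))
    r2 <- D^2 / den
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(pos[ut[, 2]] - pos[ut[, 1]])
    ok <- d <= window_bp & is.finite(r2[ut]) & n_joint[ut] > 0
    tibble::tibble(
      marker_i = ann$marker_id[ix][ut[ok, 1]],
      marker_j = ann$marker_id[ix][ut[ok, 2]],
      chrom = ann$chrom[ix][1],
      distance_bp = d[ok],
      r2 = r2[ut][ok]
    )
  })
  attr(out, "common_snps") <- ann$marker_id
  out
}

#' Greedy maximal LD binning
#'
#' Repeatedly seeds a bin at the unbinned marker with the most unbinned
#' neighbours at `r2 >= r2_threshold` (ties: smaller genomic position,
#' then marker id); the bin is the seed plus those neighbours, all of
#' which are then removed from play.  When no marker has a qualifying
#' neighbour left, the remainder become singleton bins (SNPs without
#' proxies).  Each bin's tag is chosen by [select_tag()].
#'
#' @param pairs Pair table from [pairwise_r2()].
#' @param markers Tibble of the common SNPs with columns `marker_id`,
#'   `chrom`, `pos` (defines the universe being partitioned).
#' @param r2_threshold Bin membership threshold, default 0.80.
#' @return A tibble with one row per bin: `bin_id`, `chrom`, `seed`,
#'   `tag`, `tag_avg_r2`, `n_members`, `members` (list column).
#' @export
greedy_bins <- function(pairs, markers, r2_threshold = 0.80) {
  ids <- markers$marker_id
  pos <- stats::setNames(markers$pos, ids)
  chrom <- stats::setNames(markers$chrom, ids)
  strong <- pairs[pairs$r2 >= r2_threshold, c("marker_i", "marker_j", "r2")]
  nbr <- split(c(strong$marker_j, strong$marker_i),
               c(strong$marker_i, strong$marker_j))
  unbinned <- stats::setNames(rep(TRUE, length(ids)), ids)
  bins <- list()
  # order candidates once by the tie-break (position, then id)
  tie_order <- ids[order(pos[ids], ids)]
  repeat {
    cand <- tie_order[unbinned[tie_order]]
    counts <- vapply(cand, function(m) {
      nb <- nbr[[m]]
      if (is.null(nb)) 0L else sum(unbinned[nb])
    }, integer(1))
    if (!length(counts) || max(counts) == 0L) break
    seed <- cand[which.max(counts)]   # first max in tie order
    members <- c(seed, nbr[[seed]][unbinned[nbr[[seed]]]])
    unbinned[members] <- FALSE
    bins[[length(bins) + 1L]] <- members
  }
  singletons <- names(unbinned)[unbinned]
  bins <- c(bins, as.list(singletons))
  purrr::map_dfr(seq_along(bins), function(i) {
    members <- bins[[i]]
    tg <- select_tag(members, pairs, pos)
    tibble::tibble(
      bin_id = i, chrom = unname(chrom[members[1]]), seed = members[1],
      tag = tg$tag, tag_avg_r2 = tg$avg_r2,
      n_members = length(members), members = list(sort(members))
    )
  })
}

#' Select a bin's tagSNP by the "avesnp" criterion
#'
#' The tag is the member with the maximum average r2 against all other
#' members (ties: smaller genomic position, then marker id); a singleton
#' bin tags itself.  Member pairs absent from the pair table (e.g. beyond
#' the pairing window) contribute r2 = 0 to the average.
#'
#' @param members Character vector of the bin's marker ids.
#' @param pairs Pair table from [pairwise_r2()].
#' @param pos Named position vector for the tie-break (optional).
#' @return List with `tag` and `avg_r2`.
#' @export
select_tag <- function(members, pairs, pos = NULL) {
  if (length(members) == 1) {
    return(list(tag = members, avg_r2 = NA_real_))
  }
  sub <- pairs[pairs$marker_i %in% members & pairs$marker_j %in% members, ]
  tot <- stats::setNames(numeric(length(members)), members)
  if (nrow(sub)) {
    s1 <- tapply(sub$r2, sub$marker_i, sum)
    s2 <- tapply(sub$r2, sub$marker_j, sum)
    tot[names(s1)] <- tot[names(s1)] + s1
    tot[names(s2)] <- tot[names(s2)] + s2
  }
  avg <- tot / (length(members) - 1)
  ord <- if (is.null(pos)) order(-avg, members) else order(-avg, pos[members], members)
  best <- members[ord[1]]
  list(tag = best, avg_r2 = unname(avg[best]))
}

#' LD bins from merged haploid genotypes
#'
#' Convenience wrapper: [pairwise_r2()] then [greedy_bins()].
#'
#' @inheritParams pairwise_r2
#' @param r2_threshold Bin membership threshold, default 0.80.
#' @return The bin tibble (see [greedy_bins()]), with attributes
#'   `"n_common_snps"` and `"pairs"`.
#' @export
ld_bins <- function(genotypes, annotation, maf_min = 0.05,
                    window_bp = 300000, r2_threshold = 0.80) {
  pairs <- pairwise_r2(genotypes, annotation, maf_min, window_bp)
  common <- attr(pairs, "common_snps")
  markers <- annotation[match(common, annotation$marker_id), ]
  bins <- greedy_bins(pairs, markers, r2_threshold)
  attr(bins, "n_common_snps") <- length(common)
  attr(bins, "pairs") <- pairs
  bins
}

#' Summary statistics of an LD-bin table
#'
#' @param bins Result of [ld_bins()] or [greedy_bins()].
#' @param n_common_snps Number of common SNPs (defaults to the attribute
#'   carried by [ld_bins()]).
#' @return One-row tibble with bin counts and the fraction of common SNPs
#'   without proxies (singleton members / common SNPs).
#' @export
bin_summary <- function(bins, n_common_snps = attr(bins, "n_common_snps")) {
  n_single <- sum(bins$n_members == 1)
  if (is.null(n_common_snps)) n_common_snps <- sum(bins$n_members)
  tibble::tibble(
    n_common_snps = n_common_snps,
    n_bins = nrow(bins),
    n_singleton_bins = n_single,
    fraction_without_proxies = n_single / n_common_snps
  )
}
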