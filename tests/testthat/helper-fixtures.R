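# Shared fixtures and independent oracles used across the suite.

# small, fast simulation configuration (structure as the default, scale down)
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 20, n_chroms = 2, n_blocks = 8, snps_per_block = 10,
         block_span_bp = 20000, intensity_probes_per_chrom = 20,
         duplicate_probe_count = 2, seed = seed),
    list(...)
  )
  do.call(simulation_config, args)
}

# annotation tibble builder for hand-made cases
make_ann <- function(ids, chrom, pos, a = "A", g = "G",
                     probe_class = "snp", platform = "A") {
  tibble::tibble(
    marker_id = ids, chrom = chrom, pos = as.integer(pos),
    allele_a = if (length(a) == 1) rep(a, length(ids)) else a,
    allele_b = if (length(g) == 1) rep(g, length(ids)) else g,
    probe_class = probe_class, platform = platform
  )
}

# call matrix from a character vector/matrix
make_calls <- function(x, samples = NULL, markers = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(x)))
  if (is.null(markers)) markers <- sprintf("m%02d", seq_len(ncol(x)))
  dimnames(x) <- list(samples, markers)
  genotype_matrix(x)
}

make_intens <- function(x, samples = NULL, markers = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(x)))
  if (is.null(markers)) markers <- sprintf("m%02d", seq_len(ncol(x)))
  dimnames(x) <- list(samples, markers)
  intensity_matrix(x)
}

# --- independent oracles ------------------------------------------------

# haploid r2 by direct haplotype counting on 0/1 vectors (NA = missing)
oracle_r2 <- function(u, v) {
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  p <- mean(u); q <- mean(v); f <- mean(u & v)
  den <- p * (1 - p) * q * (1 - q)
  if (den == 0) return(NA_real_)
  (f - p * q)^2 / den
}

# brute-force best circular split: plain double loop over arc boundaries
oracle_max_arc <- function(x, min_width = 2) {
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / n)
  best <- list(i = NA, j = NA, stat = 0)
  if (s == 0) return(best)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < min_width || k >= n || (n - k) < min_width) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      t_stat <- abs(mean(arc) - mean(comp)) / (s * sqrt(1 / k + 1 / (n - k)))
      if (t_stat > best$stat) best <- list(i = i, j = j, stat = t_stat)
    }
  }
  best
}

# the cut points implied by an arc (i, j]: an arc touching either end is
# one cut; an interior arc cuts twice.  Complementary arcs (i = 0 vs j = n)
# have identical statistics and identical cut sets.
arc_cuts <- function(sp, n) {
  setdiff(c(sp$i, sp$j), c(0L, n))
}

# naive greedy binning re-implementation used as the exhaustive check of
# the greedy objective on small instances
oracle_greedy <- function(pairs, markers, thr) {
  adj <- list()
  for (k in seq_len(nrow(pairs))) {
    if (pairs$r2[k] >= thr) {
      adj[[pairs$marker_i[k]]] <- c(adj[[pairs$marker_i[k]]], pairs$marker_j[k])
      adj[[pairs$marker_j[k]]] <- c(adj[[pairs$marker_j[k]]], pairs$marker_i[k])
    }
  }
  left <- markers$marker_id
  pos <- stats::setNames(markers$pos, markers$marker_id)
  bins <- list()
  repeat {
    counts <- vapply(left, function(m) length(intersect(adj[[m]], left)),
                     integer(1))
    if (!length(counts) || max(counts) == 0) break
    mx <- max(counts)
    cand <- left[counts == mx]
    seed <- cand[order(pos[cand], cand)][1]
    members <- c(seed, intersect(adj[[seed]], left))
    bins[[length(bins) + 1]] <- sort(members)
    left <- setdiff(left, members)
  }
  c(bins, as.list(left))
}
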