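# Cross-platform harmonization and merging.  Shared SNPs are matched by
# (chrom, pos); platform B annotations reported on the opposite strand are
# complemented ("flipped"); complement-invariant (A/T, C/G) SNPs are
# oriented by allele-frequency agreement or excluded; per-sample calls are
# then combined in nucleotide space, forcing discordant pairs to no-calls.

allele_freq_a <- function(genotypes) {
  g <- unclass(genotypes)
  nA <- colSums(g == "AA")
  nB <- colSums(g == "BB")
  nA / pmax(nA + nB, 1L)
}

#' Reconcile allele strands between the two platforms
#'
#' Shared SNPs are matched by `(chrom, pos)` among SNP probes.  When the
#' two allele sets agree the marker is kept as is; when platform B's
#' complemented alleles agree with platform A's the marker is flipped and
#' B's annotation complemented.  Complement-invariant SNPs (A/T and C/G)
#' cannot be oriented from alleles; with genotype matrices supplied, the
#' orientation minimizing the between-platform allele-frequency difference
#' is taken, except that the SNP is excluded as ambiguous when both
#' orientations agree within `freq_tolerance` or the SNP is rare
#' (minor-allele frequency below `rare_maf`) on either platform.
#' Irreconcilable allele sets are also excluded.
#'
#' @param ann_A,ann_B Marker annotations for the two platforms.
#' @param geno_A,geno_B Optional [genotype_matrix()]s used for the
#'   frequency rule; without them every complement-invariant shared SNP is
#'   excluded.
#' @param freq_tolerance Frequency-difference tolerance below which both
#'   orientations are considered to agree, default 0.1.
#' @param rare_maf MAF below which the frequency rule is not trusted,
#'   default 0.05.
#' @return List with `flip_set` (platform-B marker ids), `ambiguous_set`,
#'   `excluded_set` (irreconcilable), `ann_B_harmonized` (B annotation
#'   with flipped alleles complemented) and `shared` (tibble pairing the
#'   shared marker ids).
#' @export
reconcile_strands <- function(ann_A, ann_B, geno_A = NULL, geno_B = NULL,
                              freq_tolerance = 0.1, rare_maf = 0.05) {
  a <- ann_A[ann_A$probe_class == "snp", ]
  b <- ann_B[ann_B$probe_class == "snp", ]
  shared <- dplyr::inner_join(
    dplyr::select(a, id_A = "marker_id", "chrom", "pos",
                  a1_A = "allele_a", a2_A = "allele_b"),
    dplyr::select(b, id_B = "marker_id", "chrom", "pos",
                  a1_B = "allele_a", a2_B = "allele_b"),
    by = c("chrom", "pos"), relationship = "many-to-many"
  )
  fA <- if (!is.null(geno_A)) allele_freq_a(geno_A) else NULL
  fB <- if (!is.null(geno_B)) allele_freq_a(geno_B) else NULL

  n <- nrow(shared)
  flip <- logical(n); ambiguous <- logical(n); excluded <- logical(n)
  for (i in seq_len(n)) {
    setA <- c(shared$a1_A[i], shared$a2_A[i])
    setB <- c(shared$a1_B[i], shared$a2_B[i])
    invariant <- setequal(setB, COMPLEMENT[setB])
    if (invariant) {
      if (!setequal(setA, setB) ||
          is.null(fA) || is.null(fB) ||
          !(shared$id_A[i] %in% names(fA)) || !(shared$id_B[i] %in% names(fB))) {
        ambiguous[i] <- TRUE
        next
      }
      # frequency of A's allele_a on each platform under both orientations
      pA <- fA[[shared$id_A[i]]]
      pB_same <- if (shared$a1_B[i] == shared$a1_A[i]) fB[[shared$id_B[i]]]
                 else 1 - fB[[shared$id_B[i]]]
      d_same <- abs(pA - pB_same)
      d_flip <- abs(pA - (1 - pB_same))
      rare <- min(pA, 1 - pA) < rare_maf ||
        min(pB_same, 1 - pB_same) < rare_maf
      if (rare || (d_same <= freq_tolerance && d_flip <= freq_tolerance)) {
        ambiguous[i] <- TRUE
      } else if (d_flip < d_same) {
        flip[i] <- TRUE
      }
    } else if (setequal(setA, setB)) {
      # consistent strand (order may differ; calls are compared in
      # nucleotide space downstream)
    } else if (setequal(setA, unname(COMPLEMENT[setB]))) {
      flip[i] <- TRUE
    } else {
      excluded[i] <- TRUE
    }
  }
  flip_ids <- shared$id_B[flip]
  harmonized <- ann_B
  hit <- harmonized$marker_id %in% flip_ids
  harmonized$allele_a[hit] <- unname(COMPLEMENT[harmonized$allele_a[hit]])
  harmonized$allele_b[hit] <- unname(COMPLEMENT[harmonized$allele_b[hit]])
  list(
    flip_set = flip_ids,
    ambiguous_set = shared$id_B[ambiguous],
    excluded_set = shared$id_B[excluded],
    ann_B_harmonized = harmonized,
    shared = shared[!ambiguous & !excluded, c("id_A", "id_B", "chrom", "pos")]
  )
}

# translate hom calls to nucleotides via the marker's annotation row;
# het -> "H", nocall -> NA
calls_to_nucleotides <- function(g, ann) {
  idx <- match(colnames(g), ann$marker_id)
  a <- matrix(ann$allele_a[idx], nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  b <- matrix(ann$allele_b[idx], nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  out <- matrix(NA_character_, nrow = nrow(g), ncol = ncol(g),
                dimnames = dimnames(g))
  out[g == "AA"] <- a[g == "AA"]
  out[g == "BB"] <- b[g == "BB"]
  out[g == "AB"] <- "H"
  out
}

#' Merge the two platforms' genotype calls
#'
#' Produces the union of both platforms' markers.  For each shared SNP and
#' sample, the two calls are compared in nucleotide space (platform B
#' translated through its harmonized annotation): two no-calls stay a
#' no-call, a single call wins, agreeing calls are kept, and disagreeing
#' calls are forced to no-call and counted as discordant.  The discordance
#' fraction is computed over pairs where both platforms made a call.
#' Ambiguous and irreconcilable shared SNPs are dropped from the merged
#' set; platform-private markers pass through unchanged.
#'
#' @param geno_A,geno_B Post-HQC [genotype_matrix()]s with identical
#'   sample sets.
#' @param reconciliation Result of [reconcile_strands()].
#' @param ann_A Platform-A annotation (defines the merged allele frame).
#' @return List with `genotypes` (merged calls labelled in platform A's
#'   allele frame for shared SNPs), `annotation` (merged marker
#'   annotation) and `report` (a `merge_report`).
#' @export
merge_calls <- function(geno_A, geno_B, reconciliation, ann_A) {
  if (!setequal(rownames(geno_A), rownames(geno_B))) {
    stop("platform sample sets differ; filter samples jointly before merging")
  }
  gB <- unclass(geno_B)[rownames(geno_A), , drop = FALSE]
  gA <- unclass(geno_A)
  sh <- reconciliation$shared
  sh <- sh[sh$id_A %in% colnames(gA) & sh$id_B %in% colnames(gB), , drop = FALSE]
  sh <- sh[!duplicated(sh$id_A) & !duplicated(sh$id_B), , drop = FALSE]
  annB <- reconciliation$ann_B_harmonized

  nucA <- calls_to_nucleotides(gA[, sh$id_A, drop = FALSE], ann_A)
  nucB <- calls_to_nucleotides(gB[, sh$id_B, drop = FALSE], annB)
  both <- !is.na(nucA) & !is.na(nucB)
  discordant <- both & nucA != nucB
  merged_nuc <- ifelse(is.na(nucA), nucB, nucA)
  merged_nuc[discordant] <- NA_character_

  # back to AA/BB labels in platform A's frame
  idx <- match(sh$id_A, ann_A$marker_id)
  a_mat <- matrix(ann_A$allele_a[idx], nrow = nrow(gA), ncol = nrow(sh), byrow = TRUE)
  merged_sh <- matrix("NC", nrow = nrow(gA), ncol = nrow(sh),
                      dimnames = list(rownames(gA), sh$id_A))
  merged_sh[!is.na(merged_nuc) & merged_nuc == "H"] <- "AB"
  hom <- !is.na(merged_nuc) & merged_nuc != "H"
  merged_sh[hom] <- ifelse(merged_nuc[hom] == a_mat[hom], "AA", "BB")

  drop_B <- c(sh$id_B, reconciliation$ambiguous_set, reconciliation$excluded_set)
  priv_A <- setdiff(colnames(gA), sh$id_A)
  priv_B <- setdiff(colnames(gB), drop_B)
  merged <- cbind(merged_sh, gA[, priv_A, drop = FALSE], gB[, priv_B, drop = FALSE])

  ann <- dplyr::bind_rows(
    ann_A[ann_A$marker_id %in% c(sh$id_A, priv_A), ],
    annB[annB$marker_id %in% priv_B, ]
  )
  ann <- sort_annotation(ann)
  merged <- merged[, ann$marker_id, drop = FALSE]

  n_both <- sum(both)
  report <- structure(list(
    n_shared_snps = nrow(sh),
    n_flipped = length(reconciliation$flip_set),
    n_ambiguous_excluded = length(reconciliation$ambiguous_set),
    n_discordant_forced = sum(discordant),
    n_compared = n_both,
    discordance_fraction = if (n_both > 0) sum(discordant) / n_both else NA_real_
  ), class = "merge_report")
  list(genotypes = genotype_matrix(merged), annotation = ann, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report> ", x$n_shared_snps, " shared SNPs (", x$n_flipped,
      " flipped, ", x$n_ambiguous_excluded, " ambiguous excluded); ",
      x$n_discordant_forced, "/", x$n_compared,
      " discordant calls forced to no-calls\n", sep = "")
  invisible(x)
}

#' Export merged haploid calls as PLINK transposed text
#'
#' Writes `<prefix>.tped` / `<prefix>.tfam`.  Each duplicated-haploid call
#' is emitted as the same allele twice (the diploid signal is redundant in
#' CHM material); no-calls become `0 0`.  Heterozygous calls, which HQC
#' removes, are rejected here.
#'
#' @param genotypes Merged [genotype_matrix()].
#' @param annotation Matching marker annotation (SNP probes exported).
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink_tped <- function(genotypes, annotation, prefix) {
  g <- unclass(genotypes)
  if (any(g == "AB")) stop("heterozygous calls present; apply HQC first")
  ann <- annotation[annotation$probe_class == "snp" &
                    annotation$marker_id %in% colnames(g), ]
  g <- g[, ann$marker_id, drop = FALSE]
  allele <- matrix("0", nrow = nrow(g), ncol = ncol(g))
  aa <- matrix(ann$allele_a, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  bb <- matrix(ann$allele_b, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  allele[g == "AA"] <- aa[g == "AA"]
  allele[g == "BB"] <- bb[g == "BB"]
  lines <- vapply(seq_len(nrow(ann)), function(j) {
    paste(c(sub("^chr", "", ann$chrom[j]), ann$marker_id[j], 0, ann$pos[j],
            rbind(allele[, j], allele[, j])), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".tped"))
  writeLines(paste(rownames(g), rownames(g), 0, 0, 0, -9), paste0(prefix, ".tfam"))
  invisible(prefix)
}

#' @export
glance.merge_report <- function(x, ...) {
  tibble::tibble(
    n_shared_snps = x$n_shared_snps, n_flipped = x$n_flipped,
    n_ambiguous_excluded = x$n_ambiguous_excluded,
    n_discordant_forced = x$n_discordant_forced,
    n_compared = x$n_compared,
    discordance_fraction = x$discordance_fraction
  )
}
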