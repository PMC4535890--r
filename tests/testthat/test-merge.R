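test_that("strand reconciliation flips complemented annotations", {
  ann_A <- make_ann(c("a1", "a2"), "chr1", c(100, 200),
                    a = c("A", "A"), g = c("G", "G"))
  ann_B <- make_ann(c("b1", "b2"), "chr1", c(100, 200),
                    a = c("T", "A"), g = c("C", "G"), platform = "B")
  rec <- reconcile_strands(ann_A, ann_B)
  expect_equal(rec$flip_set, "b1")            # T/C is the complement of A/G
  expect_equal(rec$ambiguous_set, character(0))
  harm <- rec$ann_B_harmonized
  expect_equal(harm$allele_a[harm$marker_id == "b1"], "A")
  expect_equal(harm$allele_b[harm$marker_id == "b1"], "G")
  expect_equal(harm$allele_a[harm$marker_id == "b2"], "A")  # untouched
})

test_that("irreconcilable allele sets are excluded", {
  ann_A <- make_ann("a1", "chr1", 100, a = "A", g = "G")
  ann_B <- make_ann("b1", "chr1", 100, a = "A", g = "C", platform = "B")
  rec <- reconcile_strands(ann_A, ann_B)
  expect_equal(rec$excluded_set, "b1")
  expect_equal(nrow(rec$shared), 0)
})

test_that("ambiguous SNPs are oriented by allele frequency or excluded", {
  ann_A <- make_ann("a1", "chr1", 100, a = "A", g = "T")
  ann_B <- make_ann("b1", "chr1", 100, a = "A", g = "T", platform = "B")
  # freq_A(allele_a) = 0.10 on A; 0.89 on B -> flip (|0.10 - 0.11| < |0.10 - 0.89|)
  gA <- make_calls(matrix(c(rep("AA", 10), rep("BB", 90)), ncol = 1),
                   markers = "a1")
  gB <- make_calls(matrix(c(rep("AA", 89), rep("BB", 11)), ncol = 1),
                   markers = "b1")
  rec <- reconcile_strands(ann_A, ann_B, gA, gB, freq_tolerance = 0.1)
  expect_equal(rec$flip_set, "b1")
  expect_equal(rec$ambiguous_set, character(0))

  # both orientations agree within tolerance -> ambiguous, excluded
  gB2 <- make_calls(matrix(c(rep("AA", 50), rep("BB", 50)), ncol = 1),
                    markers = "b1")
  gA2 <- make_calls(matrix(c(rep("AA", 50), rep("BB", 50)), ncol = 1),
                    markers = "a1")
  rec2 <- reconcile_strands(ann_A, ann_B, gA2, gB2, freq_tolerance = 0.1)
  expect_equal(rec2$ambiguous_set, "b1")

  # rare on one platform -> excluded regardless of frequency fit
  gA3 <- make_calls(matrix(c(rep("AA", 2), rep("BB", 98)), ncol = 1),
                    markers = "a1")
  rec3 <- reconcile_strands(ann_A, ann_B, gA3, gB, rare_maf = 0.05)
  expect_equal(rec3$ambiguous_set, "b1")

  # no genotypes supplied: always ambiguous
  rec4 <- reconcile_strands(ann_A, ann_B)
  expect_equal(rec4$ambiguous_set, "b1")
})

test_that("merge combines calls and forces discordance to no-calls", {
  ann_A <- make_ann(c("a1", "a2", "a3"), "chr1", c(100, 200, 300))
  ann_B <- make_ann(c("b1", "b2", "b3"), "chr1", c(100, 200, 300),
                    platform = "B")
  gA <- make_calls(matrix(c("AA", "NC", "AA"), nrow = 1), samples = "s1",
                   markers = c("a1", "a2", "a3"))
  gB <- make_calls(matrix(c("NC", "BB", "BB"), nrow = 1), samples = "s1",
                   markers = c("b1", "b2", "b3"))
  rec <- reconcile_strands(ann_A, ann_B)
  res <- merge_calls(gA, gB, rec, ann_A)
  out <- unclass(res$genotypes)
  expect_equal(unname(out[1, c("a1", "a2", "a3")]), c("AA", "BB", "NC"))
  expect_equal(res$report$n_discordant_forced, 1)
  expect_equal(res$report$n_compared, 1)
  expect_equal(res$report$discordance_fraction, 1)

  # sample sets must match
  gB2 <- make_calls(matrix("AA", nrow = 1, ncol = 3), samples = "other",
                    markers = c("b1", "b2", "b3"))
  expect_error(merge_calls(gA, gB2, rec, ann_A), "sample sets differ")
})

test_that("one planted disagreement in 100 pairs gives discordance 0.01", {
  ids_A <- sprintf("a%02d", 1:10)
  ids_B <- sprintf("b%02d", 1:10)
  ann_A <- make_ann(ids_A, "chr1", seq(100, 1000, by = 100))
  ann_B <- make_ann(ids_B, "chr1", seq(100, 1000, by = 100), platform = "B")
  calls <- matrix("AA", nrow = 10, ncol = 10)
  gA <- make_calls(calls, markers = ids_A)
  callsB <- calls
  callsB[3, 7] <- "BB"
  gB <- make_calls(callsB, markers = ids_B)
  rec <- reconcile_strands(ann_A, ann_B)
  res <- merge_calls(gA, gB, rec, ann_A)
  expect_equal(res$report$n_compared, 100)
  expect_equal(res$report$discordance_fraction, 0.01)
  expect_equal(unclass(res$genotypes)[3, "a07"], "NC")
})

test_that("platform-private markers pass through and the union is merged", {
  ann_A <- make_ann(c("a1", "priv_a"), "chr1", c(100, 150))
  ann_B <- make_ann(c("b1", "priv_b"), "chr1", c(100, 250), platform = "B")
  gA <- make_calls(matrix(c("AA", "BB"), nrow = 1), samples = "s1",
                   markers = c("a1", "priv_a"))
  gB <- make_calls(matrix(c("AA", "AA"), nrow = 1), samples = "s1",
                   markers = c("b1", "priv_b"))
  rec <- reconcile_strands(ann_A, ann_B)
  res <- merge_calls(gA, gB, rec, ann_A)
  expect_setequal(colnames(res$genotypes), c("a1", "priv_a", "priv_b"))
  expect_equal(nrow(res$annotation), 3)
})

test_that("planted strand flips are recovered exactly on unambiguous SNPs", {
  for (seed in c(101, 202, 303)) {
    sim <- simulate_chm_study(small_sim_config(seed = seed, n_samples = 30))
    rec <- reconcile_strands(sim$ann_A, sim$ann_B, sim$geno_A, sim$geno_B)
    shared_B <- rec$shared$id_B
    truth_flips <- intersect(sim$truth$flipped_marker_ids, shared_B)
    expect_setequal(intersect(rec$flip_set, shared_B), truth_flips)
  }
})

test_that("merged discordance matches the 2e(1-e) expectation", {
  e <- 0.001
  sim <- simulate_chm_study(small_sim_config(
    seed = 77, n_samples = 84, n_blocks = 16, snps_per_block = 20,
    baseline_miscall_rate = e, baseline_nocall_rate = 0,
    cnv_spec = tibble::tibble(chrom = character(0), start = integer(0),
                              end = integer(0), kind = character(0),
                              carrier_fraction = numeric(0))
  ))
  rec <- reconcile_strands(sim$ann_A, sim$ann_B, sim$geno_A, sim$geno_B)
  res <- merge_calls(sim$geno_A, sim$geno_B, rec, sim$ann_A)
  expected <- 2 * e * (1 - e)
  n <- res$report$n_compared
  sd3 <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(res$report$discordance_fraction - expected), sd3)
})

test_that("merging is symmetric up to the flip convention", {
  sim <- simulate_chm_study(small_sim_config(seed = 55))
  recAB <- reconcile_strands(sim$ann_A, sim$ann_B, sim$geno_A, sim$geno_B)
  resAB <- merge_calls(sim$geno_A, sim$geno_B, recAB, sim$ann_A)
  # swap platforms: flip A's annotation into B's frame instead
  recBA <- reconcile_strands(sim$ann_B, sim$ann_A, sim$geno_B, sim$geno_A)
  resBA <- merge_calls(sim$geno_B, sim$geno_A, recBA, sim$ann_B)
  expect_equal(resAB$report$n_discordant_forced,
               resBA$report$n_discordant_forced)
  expect_equal(resAB$report$n_compared, resBA$report$n_compared)
  # identical merged calls at shared sites (labels are frame-invariant when
  # the flip preserves allele order, as here)
  shA <- recAB$shared
  shB <- recBA$shared
  m <- match(paste(shA$chrom, shA$pos), paste(shB$chrom, shB$pos))
  callsAB <- unclass(resAB$genotypes)[, shA$id_A, drop = FALSE]
  callsBA <- unclass(resBA$genotypes)[rownames(callsAB), shB$id_A[m],
                                      drop = FALSE]
  expect_true(all(callsAB == callsBA))
})
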