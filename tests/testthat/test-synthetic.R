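test_that("same seed gives identical simulations", {
  s1 <- simulate_chm_study(small_sim_config(seed = 42))
  s2 <- simulate_chm_study(small_sim_config(seed = 42))
  expect_identical(s1$geno_A, s2$geno_A)
  expect_identical(s1$intens_B, s2$intens_B)
  expect_identical(s1$truth$cnv_carriers, s2$truth$cnv_carriers)
  s3 <- simulate_chm_study(small_sim_config(seed = 43))
  expect_false(identical(unclass(s1$geno_A), unclass(s3$geno_A)))
})

test_that("degenerate ancestral pools behave as expected", {
  # pool of one haplotype: all samples identical, every site monomorphic
  cfg <- small_sim_config(seed = 5, n_haplotypes_per_block = 1, maf_floor = 0,
                          mutation_rate = 0)
  sim <- simulate_haplotypes(cfg)
  expect_true(all(apply(sim$haplotypes, 2, function(col) length(unique(col)) == 1)))

  # unattainable MAF floor
  expect_error(
    simulate_haplotypes(small_sim_config(seed = 5, n_haplotypes_per_block = 2,
                                         maf_floor = 0.8)),
    "unattainable")
})

test_that("two-haplotype pool without mutation forces r2 = 1 within blocks", {
  cfg <- small_sim_config(seed = 9, n_haplotypes_per_block = 2,
                          mutation_rate = 0, maf_floor = 0.5)
  sim <- simulate_haplotypes(cfg)
  hap01 <- sim$haplotypes == matrix(sim$sites$alt, nrow = nrow(sim$haplotypes),
                                    ncol = nrow(sim$sites), byrow = TRUE)
  for (b in split(seq_len(nrow(sim$sites)),
                  paste(sim$sites$chrom, sim$sites$block))[1:4]) {
    poly <- b[apply(hap01[, b, drop = FALSE], 2, function(u) var(u) > 0)]
    if (length(poly) < 2) next
    pairs <- utils::combn(poly, 2)
    for (k in seq_len(ncol(pairs))) {
      expect_equal(oracle_r2(hap01[, pairs[1, k]], hap01[, pairs[2, k]]), 1)
    }
  }
})

test_that("between-block r2 is near zero", {
  cfg <- small_sim_config(seed = 13, n_samples = 84)
  sim <- simulate_haplotypes(cfg)
  hap01 <- sim$haplotypes == matrix(sim$sites$alt, nrow = nrow(sim$haplotypes),
                                    ncol = nrow(sim$sites), byrow = TRUE)
  set.seed(1)
  blocks <- paste(sim$sites$chrom, sim$sites$block)
  vals <- replicate(1000, {
    i <- sample(nrow(sim$sites), 1)
    j <- sample(which(blocks != blocks[i]), 1)
    oracle_r2(hap01[, i], hap01[, j])
  })
  expect_lt(mean(vals, na.rm = TRUE), 0.05)
})

test_that("planted CNVs displace intensity means as configured", {
  cfg <- small_sim_config(
    seed = 21, noise_sd_A = 0.2,
    cnv_spec = tibble::tibble(chrom = "chr1", start = 30001, end = 70000,
                              kind = "loss", carrier_fraction = 1)
  )
  sim <- simulate_haplotypes(cfg)
  pl <- plant_cnvs_and_intensities(cfg, sim)
  x <- unclass(pl$intens_A)
  in_loss <- sim$ann_A$chrom == "chr1" & sim$ann_A$pos >= 30001 &
    sim$ann_A$pos <= 70000
  vals <- x[, in_loss]
  se <- cfg$noise_sd_A / sqrt(sum(!is.na(vals)))
  expect_lt(abs(mean(vals, na.rm = TRUE) - cfg$loss_shift_A), 3 * se)
  out_vals <- x[, !in_loss]
  expect_lt(abs(mean(out_vals, na.rm = TRUE)), 0.05)

  # gain shift just above the conventional 0.5 gain boundary
  cfg2 <- small_sim_config(
    seed = 22, noise_sd_A = 0.1,
    cnv_spec = tibble::tibble(chrom = "chr1", start = 30001, end = 70000,
                              kind = "gain", carrier_fraction = 1),
    gain_shift_A = 0.58
  )
  sim2 <- simulate_haplotypes(cfg2)
  pl2 <- plant_cnvs_and_intensities(cfg2, sim2)
  in_gain <- sim2$ann_A$chrom == "chr1" & sim2$ann_A$pos >= 30001 &
    sim2$ann_A$pos <= 70000
  expect_gt(mean(unclass(pl2$intens_A)[, in_gain], na.rm = TRUE), 0.5)
})

test_that("opposite-kind overlapping CNVs in one carrier are rejected", {
  cfg <- small_sim_config(
    seed = 3,
    cnv_spec = tibble::tibble(chrom = "chr1", start = c(30001, 50001),
                              end = c(70000, 90000), kind = c("loss", "gain"),
                              carrier_fraction = c(1, 1))
  )
  sim <- simulate_haplotypes(cfg)
  expect_error(plant_cnvs_and_intensities(cfg, sim), "opposite kind")
})

test_that("false het calls concentrate in carried losses", {
  loss <- tibble::tibble(chrom = "chr1", start = 10001, end = 90000,
                         kind = "loss", carrier_fraction = 1)
  cfg0 <- small_sim_config(seed = 31, cnv_spec = loss,
                           false_het_rate_in_loss = 0,
                           baseline_miscall_rate = 0.001)
  sim0 <- simulate_chm_study(cfg0)
  expect_equal(sum(unclass(sim0$geno_A) == "AB"), 0)

  cfg <- small_sim_config(seed = 31, cnv_spec = loss,
                          false_het_rate_in_loss = 0.4)
  sim <- simulate_chm_study(cfg)
  snp_ann <- sim$ann_A[sim$ann_A$probe_class == "snp", ]
  in_loss <- snp_ann$chrom == "chr1" & snp_ann$pos >= 10001 &
    snp_ann$pos <= 90000
  calls <- unclass(sim$geno_A)[, snp_ann$marker_id[in_loss]]
  het_frac <- mean(calls == "AB")
  n <- length(calls)
  expect_lt(abs(het_frac - 0.4), 3 * sqrt(0.4 * 0.6 / n))
})

test_that("simulated allele frequencies track pool frequencies", {
  cfg <- small_sim_config(seed = 8, n_samples = 84, mutation_rate = 0)
  sim <- simulate_haplotypes(cfg)
  # realized alt-allele frequency must stay within binomial error of a
  # legal pool frequency (pool counts are multiples of 1/pool size)
  hap01 <- sim$haplotypes == matrix(sim$sites$alt, nrow = nrow(sim$haplotypes),
                                    ncol = nrow(sim$sites), byrow = TRUE)
  freqs <- colMeans(hap01)
  pool_freqs <- seq(0, cfg$n_haplotypes_per_block) / cfg$n_haplotypes_per_block
  dist <- vapply(freqs, function(f) min(abs(f - pool_freqs)), numeric(1))
  tol <- 3 * sqrt(0.5 * 0.5 / cfg$n_samples)
  expect_true(all(dist <= tol))
  # and the MAF floor holds in the pool, so hardly any site is monomorphic
  expect_lt(mean(freqs %in% c(0, 1)), 0.05)
})

test_that("emitted matrices survive the text round-trip", {
  sim <- simulate_chm_study(small_sim_config(seed = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_matrix(file.path(dir, "genotypes_A.tsv"), "genotype")
  expect_equal(unclass(g), unclass(sim$geno_A))
  x <- read_matrix(file.path(dir, "intensity_B.tsv"), "intensity")
  expect_equal(unclass(x), unclass(sim$intens_B), tolerance = 1e-12)
  ann <- read_marker_annotation(file.path(dir, "annotation_B.tsv"), "B")
  expect_equal(ann$marker_id, sim$ann_B$marker_id)
})
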