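test_that("constant profiles yield a single segment with the constant mean", {
  seg <- cbs_segment(rep(0.25, 30), seq(1000, by = 1000, length.out = 30),
                     seed = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_intensity, 0.25)
  expect_equal(seg$n_markers, 30)
  expect_equal(seg$start, 1000)
  expect_equal(seg$end, 30000)
  expect_error(cbs_segment(c(NA, NA), c(1, 2)), "no non-missing")
})

test_that("a clean step is split exactly between the two levels", {
  x <- c(rep(0, 10), rep(-3, 10))
  pos <- seq(100, by = 100, length.out = 20)
  seg <- cbs_segment(x, pos, seed = 5)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(10, 10))
  expect_equal(seg$mean_intensity, c(0, -3))
  expect_equal(seg$end[1], pos[10])
  expect_equal(seg$start[2], pos[11])

  # and the raw arc maximizer agrees with the brute-force oracle
  sp <- cbs_max_split(x)
  or <- oracle_max_arc(x)
  expect_equal(sp$i, or$i)
  expect_equal(sp$j, or$j)
  expect_equal(sp$stat, or$stat, tolerance = 1e-12)
})

test_that("max-arc statistic matches brute force on random instances", {
  set.seed(77)
  for (k in 1:60) {
    n <- sample(6:50, 1)
    x <- rnorm(n)
    if (runif(1) < 0.5) {
      a <- sort(sample(n, 2))
      x[a[1]:a[2]] <- x[a[1]:a[2]] + sample(c(-3, 3), 1)
    }
    sp <- cbs_max_split(x)
    or <- oracle_max_arc(x)
    expect_equal(sp$stat, or$stat, tolerance = 1e-10)
    expect_equal(arc_cuts(sp, n), arc_cuts(or, n))
  }
})

test_that("missing values are dropped before segmentation", {
  x <- c(0, NA, rep(0, 5), NA, rep(-3, 6), rep(0, 7))
  pos <- seq(10, by = 10, length.out = length(x))
  seg <- cbs_segment(x, pos, seed = 2, n_perm = 2000)
  expect_equal(sum(seg$n_markers), sum(!is.na(x)))
  low <- seg[seg$mean_intensity < -1, ]
  expect_equal(low$start, 90)    # first marker of the -3 run
  expect_equal(low$end, 140)     # last marker of the -3 run
})

test_that("pure noise is rarely split at alpha 0.01", {
  set.seed(99)
  n_split <- 0
  for (k in 1:40) {
    x <- rnorm(120)
    seg <- cbs_segment(x, seq_along(x), alpha = 0.01, n_perm = 10000, seed = k)
    if (nrow(seg) > 1) n_split <- n_split + 1
  }
  expect_lte(n_split / 40, 0.10)
})

test_that("segments partition the observed markers", {
  sim <- simulate_chm_study(small_sim_config(seed = 23, n_samples = 8))
  ann <- sim$ann_A[sim$ann_A$chrom == "chr1", ]
  ann <- ann[order(ann$pos, ann$marker_id), ]
  v <- unclass(sim$intens_A)["CHM001", ann$marker_id]
  seg <- cbs_segment(v, ann$pos, n_perm = 2000, seed = 3)
  expect_equal(sum(seg$n_markers), sum(!is.na(v)))
  expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
})

test_that("centromere splitting clips, recomputes and drops empty parts", {
  seg <- tibble::tibble(sample_id = "s1", platform = "A", chrom = "chr1",
                        start = 100L, end = 900L, n_markers = 9L,
                        mean_intensity = -2)
  gm <- tibble::tibble(chrom = "chr1", length_bp = 1000L,
                       centromere_start = 400L, centromere_end = 600L)
  out <- split_at_centromere(seg, gm)
  expect_equal(out$start, c(100L, 601L))
  expect_equal(out$end, c(399L, 900L))

  # untouched when inside one arm
  seg2 <- dplyr::mutate(seg, start = 650L, end = 900L)
  expect_equal(split_at_centromere(seg2, gm), seg2)

  # entirely inside the centromere: dropped
  seg3 <- dplyr::mutate(seg, start = 450L, end = 550L)
  expect_equal(nrow(split_at_centromere(seg3, gm)), 0)

  # with marker data: means recomputed per part, coordinates snapped
  ann <- make_ann(paste0("m", 1:6), "chr1", c(100, 200, 399, 601, 700, 900))
  x <- make_intens(matrix(c(-3, -3, -3, 0, 0, 0), nrow = 1),
                   samples = "s1", markers = paste0("m", 1:6))
  out2 <- split_at_centromere(seg, gm, x, ann)
  expect_equal(out2$mean_intensity, c(-3, 0))
  expect_equal(out2$n_markers, c(3L, 3L))
  expect_equal(out2$start, c(100L, 601L))
  expect_equal(out2$end, c(399L, 900L))
})

test_that("coverage profile accumulates bp into mean-intensity bins", {
  seg <- tibble::tibble(sample_id = "s", platform = "A", chrom = "chr1",
                        start = c(1L, 2001L, 5001L),
                        end = c(1000L, 2300L, 5700L),
                        n_markers = 3L,
                        mean_intensity = c(-3, -2.95, 0.02))
  prof <- coverage_profile(seg)
  expect_s3_class(prof, "segment_coverage_profile")
  b1 <- prof[abs(prof$bin_lower - (-3)) < 1e-9, ]
  expect_equal(b1$bp_covered, 1000 + 300)   # same bin: lengths add
  b2 <- prof[abs(prof$bin_lower - 0) < 1e-9, ]
  expect_equal(b2$bp_covered, 700)
  expect_equal(sum(prof$bp_covered), 2000)  # total bp conserved
  expect_equal(prof$cumulative_bp[nrow(prof)], 2000)
})

test_that("loss threshold sits in the coverage minimum between the modes", {
  seg <- tibble::tibble(
    sample_id = "s", platform = "A", chrom = "chr1",
    start = c(1L, 10001L, 20001L), end = c(5000L, 10400L, 520000L),
    n_markers = 5L, mean_intensity = c(-3.05, -2.95, 0.01)
  )
  prof <- coverage_profile(seg)
  thr <- find_loss_threshold(prof)
  expect_gte(thr, -2.9)
  expect_lte(thr, 0)
  # and with empty bins only in (-2, -1), the threshold falls there
  seg2 <- dplyr::bind_rows(
    seg,
    tibble::tibble(sample_id = "s", platform = "A", chrom = "chr1",
                   start = 600001L, end = 600500L, n_markers = 3L,
                   mean_intensity = -0.55)
  )
  prof2 <- coverage_profile(seg2)
  thr2 <- find_loss_threshold(prof2)
  expect_gte(thr2, -2.9)
  expect_lte(thr2, -0.5)

  # no segment mean below zero: sentinel
  seg3 <- seg[3, ]
  expect_identical(find_loss_threshold(coverage_profile(seg3)), -Inf)

  # a lone low bin with nothing near zero cannot be bracketed
  seg4 <- seg[1, ]
  expect_error(find_loss_threshold(coverage_profile(seg4)), "cannot bracket")
})

test_that("classification uses strict thresholds and the size filter", {
  seg <- tibble::tibble(
    sample_id = "s", platform = "A", chrom = "chr1",
    start = c(1L, 1001L, 2001L, 3001L, 4001L),
    end = c(600L, 2000L, 2051L, 3050L, 4600L),
    n_markers = 3L,
    mean_intensity = c(-1.2, -1.0, -1.3, -1.3, 0.7)
  )
  out <- classify_and_filter(seg, loss_threshold = -1, gain_threshold = 0.5,
                             min_size_bp = 50)
  # -1.2 -> loss; exactly -1.0 -> neutral (strict); 51 bp kept, 50 bp dropped
  expect_setequal(out$state[out$mean_intensity < -1], "loss")
  expect_false(any(out$mean_intensity == -1))
  expect_true(any(out$start == 2001L))    # 51 bp loss kept
  expect_false(any(out$start == 3001L))   # 50 bp loss removed
  expect_equal(out$state[out$mean_intensity == 0.7], "gain")

  withn <- classify_and_filter(seg, -1, keep_neutral = TRUE)
  expect_true("neutral" %in% withn$state)
  expect_error(classify_and_filter(seg, 0.6, gain_threshold = 0.5),
               "loss_threshold")
})

test_that("planted losses are recovered with tight breakpoints", {
  cfg <- small_sim_config(
    seed = 41, n_samples = 6, n_chroms = 1, n_blocks = 8,
    snps_per_block = 20, block_span_bp = 30000,
    intensity_probes_per_chrom = 40, missing_intensity_rate = 0,
    cnv_spec = tibble::tibble(chrom = "chr1", start = 70001, end = 130000,
                              kind = "loss", carrier_fraction = 0.5)
  )
  sim <- simulate_chm_study(cfg)
  seg <- segment_platform(sim$intens_A, sim$ann_A, platform = "A",
                          master_seed = 41)
  seg <- split_at_centromere(seg, sim$genome, sim$intens_A, sim$ann_A)
  thr <- find_loss_threshold(coverage_profile(seg))
  expect_gt(thr, cfg$loss_shift_A)
  expect_lt(thr, 0)
  cnv <- classify_and_filter(seg, thr)
  carriers <- unique(sim$truth$cnv_carriers$sample_id)
  ann <- sim$ann_A[order(sim$ann_A$pos), ]
  in_truth <- which(ann$pos >= 70001 & ann$pos <= 130000)
  for (s in carriers) {
    hit <- cnv[cnv$sample_id == s & cnv$state == "loss", ]
    expect_equal(nrow(hit), 1)
    got <- which(ann$pos >= hit$start & ann$pos <= hit$end)
    expect_lte(abs(min(got) - min(in_truth)), 2)
    expect_lte(abs(max(got) - max(in_truth)), 2)
  }
})
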