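test_that("reference haplotypes keep homozygous, top-quality markers only", {
  set.seed(5)
  n <- 300
  v <- data.frame(chrom = "chr14", pos = seq_len(n) * 100,
                  ref = "A", alt = "G",
                  qual = 999, mq = 60, consequence = "intron_variant")
  g <- matrix(sample(c(0L, 2L), n * 2, replace = TRUE), ncol = 2)
  vs <- make_vs(v, g, c("ref_animal", "other"))
  rh <- build_reference_haplotype(vs, "ref_animal")
  expect_equal(nrow(rh$markers), n)
  expect_equal(rh$allele, unname(g[, 1] / 2L))

  # heterozygous markers are dropped with a warning
  g2 <- g; g2[10, 1] <- 1L
  expect_warning(rh2 <- build_reference_haplotype(
    make_vs(v, g2, c("ref_animal", "other")), "ref_animal"),
    "heterozygous")
  expect_equal(nrow(rh2$markers), n - 1)

  # only QUAL = 999 markers are retained under the default threshold
  v3 <- v; v3$qual[1:250] <- 500
  expect_error(build_reference_haplotype(
    make_vs(v3, g, c("ref_animal", "other")), "ref_animal"),
    "at least 100")
  v3$qual[1:100] <- 999
  rh3 <- build_reference_haplotype(
    make_vs(v3, g, c("ref_animal", "other")), "ref_animal")
  expect_equal(nrow(rh3$markers), 150)
})

test_that("inconsistency counts opposing homozygotes only", {
  allele <- rep(c(0L, 1L), 50) # 100 markers
  ref <- structure(list(markers = data.frame(chrom = "chr14",
                                             pos = seq_len(100) * 10),
                        allele = allele, qual_min = 999),
                   class = "reference_haplotype")
  # identical homozygote: rate 0
  expect_equal(window_inconsistency_rate(2L * allele, ref, 1:100), 0)
  # heterozygous everywhere: never in opposition
  expect_equal(window_inconsistency_rate(rep(1L, 100), ref, 1:100), 0)
  # 10 opposing homozygotes among 100 markers
  g <- 2L * allele
  g[1:10] <- 2L * (1L - allele[1:10])
  expect_equal(window_inconsistency_rate(g, ref, 1:100), 0.10)
  # missing markers drop from numerator and denominator
  g[11:60] <- NA
  expect_equal(window_inconsistency_rate(g, ref, 1:100), 10 / 50)
  expect_true(is.na(window_inconsistency_rate(rep(NA_integer_, 100), ref,
                                              1:100)))
})

test_that("scan profiles anchor at the central marker and are label-symmetric", {
  set.seed(8)
  p <- simulate_carrier_panel(n_carriers = 4, n_hom = 1, n_controls = 0,
                              g = 50, n_markers = 400, spacing_bp = 250)
  prof <- scan_profiles(p$geno_carriers, p$reference)
  # anchor of the first window is the 51st marker
  expect_equal(prof$anchor_index[1], 51L)
  expect_equal(prof$anchor_pos, p$reference$markers$pos[prof$anchor_index])
  expect_equal(nrow(prof), 400 - 100 + 1)

  # the reference scanned against itself is everywhere consistent
  self <- scan_profiles(matrix(2L * p$reference$allele, nrow = 1),
                        p$reference)
  expect_true(all(self$n_flagged == 0))

  # swapping allele labels consistently leaves the profile unchanged
  ref_sw <- p$reference
  ref_sw$allele <- 1L - ref_sw$allele
  prof_sw <- scan_profiles(2L - p$geno_carriers, ref_sw)
  expect_equal(prof_sw$n_flagged, prof$n_flagged)

  # determinism: the same cohort scans identically
  expect_equal(scan_profiles(p$geno_carriers, p$reference)$n_flagged,
               prof$n_flagged)
})

test_that("block detection finds the zero-count run containing the focal site", {
  prof <- make_profile(c(2, 0, 0, 0, 3))
  blk <- detect_ibd_block(prof, 300)
  expect_false(blk$empty)
  expect_equal(c(blk$start, blk$end), c(200, 400))
  expect_equal(blk$n_windows, 3L)
  expect_equal(blk$length_bp, 200)

  # all consistent: the block spans every anchor
  all0 <- detect_ibd_block(make_profile(rep(0, 5)), 300)
  expect_equal(c(all0$start, all0$end), c(100, 500))

  # inconsistency at the focal window: empty block with a diagnostic
  bad <- detect_ibd_block(make_profile(c(0, 0, 4, 0, 0)), 300)
  expect_true(bad$empty)
  expect_match(bad$reason, "no shared segment")
  expect_error(date_mutation(bad), "empty")

  expect_error(detect_ibd_block(prof, 9999), "outside")
})

test_that("planted ancestral segments are recovered within one window span", {
  # resolution: a bound can only be located to within one 100-marker
  # window; seeds whose planted intersection side is narrower than a
  # window are below the method's resolution and are not scored
  n_scored <- 0
  for (seed in 1:20) {
    set.seed(seed)
    p <- simulate_carrier_panel(n_carriers = 10, n_hom = 1, n_controls = 0,
                                g = 25, n_markers = 4000, spacing_bp = 250)
    window_bp <- 100 * 250
    tr <- p$truth$intersection
    if (tr["start"] > p$focal_pos - window_bp ||
        tr["end"] < p$focal_pos + window_bp) next
    prof <- scan_profiles(p$geno_carriers, p$reference)
    blk <- detect_ibd_block(prof, p$focal_pos)
    expect_false(blk$empty, info = paste("seed", seed))
    expect_lt(abs(blk$start - tr["start"]), window_bp)
    expect_lt(abs(blk$end - tr["end"]), window_bp)
    n_scored <- n_scored + 1
  }
  expect_gte(n_scored, 10)
})

test_that("the detected block shrinks as carriers are added", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- simulate_carrier_panel(n_carriers = 12, n_hom = 1, n_controls = 0,
                                g = 25, n_markers = 3000, spacing_bp = 250)
    lens <- sapply(c(3, 6, 12), function(k) {
      prof <- scan_profiles(p$geno_carriers[1:k, , drop = FALSE],
                            p$reference)
      blk <- detect_ibd_block(prof, p$focal_pos)
      if (blk$empty) 0 else blk$length_bp
    })
    expect_true(all(diff(lens) <= 0), info = paste("seed", seed))
  }
})

test_that("control cohorts show no shared segment at the focal site", {
  flagged_at_focal <- 0
  for (seed in 1:20) {
    set.seed(seed + 400)
    p <- simulate_carrier_panel(n_carriers = 1, n_hom = 0, n_controls = 15,
                                g = 25, n_markers = 1000, spacing_bp = 250)
    prof <- control_scan(p$geno_controls, p$reference)
    at_focal <- prof$n_flagged[which.min(abs(prof$anchor_pos - p$focal_pos))]
    if (at_focal > 0) flagged_at_focal <- flagged_at_focal + 1
  }
  expect_gte(flagged_at_focal, 19)

  set.seed(1)
  p <- simulate_carrier_panel(n_carriers = 1, n_hom = 0, n_controls = 0,
                              g = 25, n_markers = 500, spacing_bp = 250)
  expect_warning(prof0 <- control_scan(p$geno_controls, p$reference),
                 "empty control cohort")
  expect_true(all(prof0$n_flagged == 0))
})
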