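test_that("window haplotypes are fixed-length strings with missing flags", {
  set.seed(31)
  markers <- data.frame(chrom = "chr14", pos = seq_len(60) * 1000)
  h1 <- matrix(rbinom(120, 1, 0.5), 60, 2)
  h2 <- matrix(rbinom(120, 1, 0.5), 60, 2)
  h2[5, 2] <- NA
  hm <- haplotype_matrix(markers, h1, h2, c("b1", "b2"))
  haps <- extract_window_haplotypes(hm, 1:50)
  expect_equal(nchar(c(haps$hap1, haps$hap2)), rep(50L, 4L))
  expect_equal(haps$complete, c(TRUE, FALSE))
  expect_equal(haps$hap1[1], paste(h1[1:50, 1], collapse = ""))
  expect_error(extract_window_haplotypes(hm, 1:40), "expected 50")
  expect_error(extract_window_haplotypes(hm, 31:80), "out of range")

  # identical haplotypes collapse to one distinct string
  hm2 <- haplotype_matrix(markers, cbind(h1[, 1], h1[, 1]),
                          cbind(h1[, 1], h1[, 1]), c("b1", "b2"))
  haps2 <- extract_window_haplotypes(hm2, 1:50)
  expect_equal(length(unique(c(haps2$hap1, haps2$hap2))), 1L)
})

test_that("haplotype status follows the homozygote-anchoring rules", {
  H <- function(k) strrep(as.character(k), 50)
  # H1 only in Fs/Fs animals; H2 in both homozygote classes; H3 only Wt/Wt;
  # H4 only in a heterozygote
  haps <- data.frame(
    sample = c("a", "b", "c", "d"),
    hap1 = c(H(1), H(1), H(2), H(3)),
    hap2 = c(H(1), H(2), H(3), H(4)),
    complete = TRUE, stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     focal_genotype = c("Fs/Fs", "Fs/Fs", "Wt/Wt", "Fs/Wt"))
  tab <- classify_haplotypes(haps, meta)
  st <- setNames(tab$status, tab$haplotype)
  expect_equal(unname(st[H(1)]), "Fs")
  expect_equal(unname(st[H(2)]), "undetermined") # seen in both classes
  expect_equal(unname(st[H(3)]), "Wt")
  expect_equal(unname(st[H(4)]), "undetermined") # het-only, unanchored
  expect_equal(haplotype_status(H(9), tab), "not_documented")

  # classified fractions partition to one
  expect_equal(sum(attr(tab, "fractions")), 1)

  # the optional heterozygote deduction anchors H4 as Fs via its Wt partner
  tab2 <- classify_haplotypes(haps, meta, deduce_het = TRUE)
  expect_equal(tab2$status[tab2$haplotype == H(4)], "Fs")

  expect_error(classify_haplotypes(
    haps, transform(meta, focal_genotype = "Fs/Wt")), "homozygous")
})

test_that("genotype inference maps status pairs and flags unknowns", {
  H <- function(k) strrep(as.character(k), 50)
  tab <- structure(data.frame(haplotype = c(H(1), H(3), H(2)),
                              n_fsfs = c(2L, 0L, 1L),
                              n_fswt = 0L,
                              n_wtwt = c(0L, 2L, 1L),
                              status = c("Fs", "Wt", "undetermined"),
                              stringsAsFactors = FALSE),
                   class = c("haplotype_status_table", "data.frame"))
  q <- data.frame(sample = c("x", "y", "z", "w"),
                  hap1 = c(H(1), H(1), H(2), H(9)),
                  hap2 = c(H(3), H(1), H(3), H(3)),
                  complete = TRUE, stringsAsFactors = FALSE)
  inf <- infer_variant_genotype(q, tab)
  expect_equal(inf$genotype, c("Fs/Wt", "Fs/Fs", "unknown", "unknown"))
  expect_equal(inf$status2[4], "Wt")
  expect_equal(inf$status1[4], "not_documented")
})

test_that("simulated cohorts are inferred exactly when anchored", {
  set.seed(77)
  tc <- simulate_trajectory_cohort(years = 1990:1999, n_per_year = 40)
  haps <- extract_window_haplotypes(tc$hm, 1:50)
  tab <- classify_haplotypes(haps, tc$meta)
  # no Fs/Fs reference animal may carry a Wt-status haplotype
  expect_true(all(tab$n_fsfs[tab$status == "Wt"] == 0))
  expect_true(all(tab$n_wtwt[tab$status == "Fs"] == 0))
  inf <- infer_variant_genotype(haps, tab)
  anchored <- inf$genotype != "unknown"
  expect_gt(mean(anchored), 0.8)
  expect_equal(inf$genotype[anchored], tc$meta$focal_genotype[anchored])
})

test_that("trajectories average informative haplotypes over year windows", {
  # one window: 5 animals Fs/Wt-anchored mix giving 10 Fs / 30 Wt
  statuses <- data.frame(
    sample = sprintf("s%02d", 1:20),
    status1 = rep(c("Fs", "Wt"), c(10, 10)),
    status2 = "Wt", stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:20), birth_year = 2000)
  tr <- frequency_trajectory(statuses, meta)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$freq, 10 / 40)
  expect_equal(tr$n_informative, 40)

  # all uninformative: window emitted with absent frequency
  st0 <- transform(statuses, status1 = "undetermined",
                   status2 = "not_documented")
  tr0 <- frequency_trajectory(st0, meta)
  expect_true(is.na(tr0$freq))
  expect_equal(tr0$n_informative, 0)

  expect_error(frequency_trajectory(statuses,
                                    transform(meta, birth_year = NA)),
               "birth year")

  # animal order does not matter; a coarser step subsamples the same curve
  set.seed(13)
  tc <- simulate_trajectory_cohort(years = 1980:2000, n_per_year = 20)
  haps <- extract_window_haplotypes(tc$hm, 1:50)
  tab <- classify_haplotypes(haps, tc$meta)
  inf <- infer_variant_genotype(haps, tab)
  tr1 <- frequency_trajectory(inf, tc$meta)
  perm <- sample(nrow(inf))
  tr2 <- frequency_trajectory(inf[perm, ], tc$meta)
  expect_equal(tr1$freq, tr2$freq)
  tr3 <- frequency_trajectory(inf, tc$meta, step_years = 3)
  expect_equal(tr3$freq, tr1$freq[match(tr3$center_year, tr1$center_year)])
})
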