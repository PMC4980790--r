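cfg <- screen_config()

test_that("candidate-consequence rule keeps LoF terms and SIFT-0 missense", {
  expect_true(is_candidate_consequence("frameshift_variant", NA, cfg))
  expect_true(is_candidate_consequence("stop_gained", NA, cfg))
  expect_true(is_candidate_consequence("missense_variant", 0, cfg))
  # a tolerated-but-low SIFT score is not retained under the default
  expect_false(is_candidate_consequence("missense_variant", 0.03, cfg))
  expect_false(is_candidate_consequence("missense_variant", NA, cfg))
  expect_false(is_candidate_consequence("synonymous_variant", NA, cfg))
  expect_false(is_candidate_consequence(NA, NA, cfg))
})

test_that("site-quality rule enforces strict QUAL/missingness and MQ set", {
  base <- data.frame(chrom = "c", pos = 1:5, ref = "A", alt = "G",
                     qual = c(999, 30, 30.01, 999, 999),
                     mq = c(60, 60, 59, 58, NA),
                     consequence = "frameshift_variant")
  geno <- matrix(0L, 5, 20)
  vs <- make_vs(base, geno)
  expect_equal(passes_site_quality(vs, cfg),
               c(TRUE, FALSE, TRUE, FALSE, FALSE))

  # exactly 5% missing fails (strict <), just under passes
  g2 <- matrix(0L, 2, 20)
  g2[1, 1] <- NA # 1/20 = 5%
  vs2 <- make_vs(base[c(1, 1), ], g2)
  expect_equal(passes_site_quality(vs2, cfg), c(FALSE, TRUE))
})

test_that("per-breed allele stats match hand counts and omit empty breeds", {
  # one breed of 23 animals: 2 hom-alt + 10 het -> 14 / 46
  geno <- matrix(0L, 1, 28)
  geno[1, 1:2] <- 2L
  geno[1, 3:12] <- 1L
  geno[1, 24:28] <- NA # breed B entirely missing at this site
  panel <- breed_panel(paste0("s", 1:28), rep(c("NOR", "B"), c(23, 5)))
  vs <- make_vs(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                           qual = 999, mq = 60,
                           consequence = "frameshift_variant"),
                geno, paste0("s", 1:28))
  st <- per_breed_allele_stats(vs, panel)
  expect_equal(nrow(st), 1L) # breed B omitted
  expect_equal(st$breed, "NOR")
  expect_equal(st$alt_count, 14)
  expect_equal(st$n_genotyped, 23)
  expect_equal(st$freq, 14 / 46)

  # all hom-ref -> frequency 0
  vs0 <- make_vs(vs$variants, matrix(0L, 1, 28), paste0("s", 1:28))
  expect_equal(per_breed_allele_stats(vs0, panel)$freq, c(0, 0))
})

test_that("same-codon conflicts pair SNVs by gene and codon only", {
  v <- data.frame(chrom = "c", pos = 1:4,
                  ref = c("A", "C", "G", "AT"),
                  alt = c("G", "T", "A", "A"),
                  qual = 999, mq = 60, consequence = "missense_variant",
                  sift = 0,
                  gene = c("RP1", "RP1", "OTHER", "RP1"),
                  codon = c(791L, 791L, 791L, 791L))
  vs <- make_vs(v, matrix(0L, 4, 2))
  cc <- same_codon_conflicts(vs)
  expect_equal(nrow(cc$pairs), 1L) # the indel and the other-gene SNV drop out
  expect_setequal(cc$excluded, vs$variants$variant_id[1:2])

  v$gene <- c("A1", "A2", "A3", "A4")
  expect_equal(length(same_codon_conflicts(make_vs(v, matrix(0L, 4, 2)))$excluded), 0L)
})

test_that("the planned screen fixture is filtered exactly as constructed", {
  set.seed(42)
  fix <- simulate_screen_vcf()
  vs <- read_vcf(fix$vcf)
  panel <- read_breed_map(fix$breeds)
  reps <- read_repeat_bed(fix$bed)
  rep_ <- apply_screen(vs, panel, reps)
  res <- rep_$results[match(fix$truth$variant_id, rep_$results$variant_id), ]
  expect_equal(res$pass, fix$truth$intended_pass)
  expect_equal(res$first_fail, fix$truth$fail_rule)
  # a 4.9%-everywhere variant fails the frequency rule
  expect_equal(res$first_fail[fix$truth$mode == "low_maf"], "maf")
  # a single observation of the alternate allele is discarded
  expect_equal(res$first_fail[fix$truth$mode == "singleton"], "singleton")
})

test_that("cascade equals an independent brute-force oracle on random fixtures", {
  set.seed(101)
  panel <- breed_panel(sprintf("s%03d", 1:75), rep(c("A", "B", "C"), each = 25))
  for (rep_i in 1:5) {
    sim <- simulate_random_variants(200, panel)
    got <- apply_screen(sim$vs, panel, sim$repeats)
    expect_equal(got$results$pass,
                 oracle_screen_pass(sim$vs, panel, sim$repeats),
                 info = paste("random fixture", rep_i))
  }
})

test_that("screen is conservative, order-independent and idempotent", {
  set.seed(202)
  panel <- breed_panel(sprintf("s%03d", 1:75), rep(c("A", "B", "C"), each = 25))
  sim <- simulate_random_variants(120, panel)
  rep1 <- apply_screen(sim$vs, panel, sim$repeats)

  # conservation: per-rule removals plus passes account for every variant
  expect_equal(sum(rep1$removed) + rep1$n_pass, n_variants(sim$vs))

  # order independence of the pass/fail set
  perm <- sample(n_variants(sim$vs))
  vs_p <- variant_set(sim$vs$variants[perm, ],
                      sim$vs$geno[perm, , drop = FALSE], sim$vs$samples)
  rep2 <- apply_screen(vs_p, panel, sim$repeats)
  expect_setequal(rep2$results$variant_id[rep2$results$pass],
                  rep1$results$variant_id[rep1$results$pass])

  # idempotence: screening the passing subset changes nothing
  keep <- rep1$results$pass
  if (any(keep)) {
    vs_k <- variant_set(sim$vs$variants[keep, ],
                        sim$vs$geno[keep, , drop = FALSE], sim$vs$samples)
    rep3 <- apply_screen(vs_k, panel, sim$repeats)
    expect_true(all(rep3$results$pass))
  }

  # shuffling sample order leaves the outcome unchanged
  sp <- sample(length(sim$vs$samples))
  vs_s <- variant_set(sim$vs$variants, sim$vs$geno[, sp, drop = FALSE],
                      sim$vs$samples[sp])
  rep4 <- apply_screen(vs_s, panel, sim$repeats)
  expect_equal(rep4$results$pass, rep1$results$pass)
})

test_that("breed sharing summaries count breeds above threshold", {
  # 3 eligible breeds of 25; v1 at >=5% in A and B, v2 only in C
  geno <- matrix(0L, 2, 75)
  geno[1, 1:5] <- 1L    # A: 10%
  geno[1, 26:30] <- 1L  # B: 10%
  geno[2, 51:60] <- 1L  # C: 20%
  panel <- breed_panel(sprintf("s%03d", 1:75), rep(c("A", "B", "C"), each = 25))
  vs <- make_vs(data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "G",
                           qual = 999, mq = 60,
                           consequence = "frameshift_variant",
                           gene = c("G1", "G2")),
                geno, sprintf("s%03d", 1:75))
  rep_ <- apply_screen(vs, panel)
  expect_true(all(rep_$results$pass))
  expect_equal(rep_$results$n_breeds_shared, c(2L, 1L))
  sh <- breed_sharing_summary(rep_)
  expect_equal(sh$frac_shared_multi, 0.5)
  expect_equal(sh$frac_shared_all, 0)
  expect_equal(unname(sh$histogram["A", "2"]), 1L)
  expect_equal(unname(sh$histogram["C", "1"]), 1L)
  expect_equal(unname(sh$histogram["C", "2"]), 0L)

  expect_error(apply_screen(vs, list()), "breed panel")
})
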