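#' Simulate two-sided IBD segment lengths under the recombination clock
#'
#' Each lineage descending g generations from the founder erodes the
#' ancestral haplotype by recombination; the retained length on each side
#' of the focal site is exponential with rate 2g per Morgan, so the
#' two-sided length L + R has mean 1/g and the pairwise dating formula
#' 1/(2c) is its generative inverse (E[1/(2c)] = g for c ~ Gamma(2, 2g)).
#'
#' Draws come from the session RNG: call `set.seed()` for reproducibility.
#'
#' @param n number of segments.
#' @param g true age in generations (> 0).
#' @param region_morgans optional `c(left, right)` distances (Morgans) from
#'   the focal site to the simulated region's edges; sides are truncated
#'   there and flagged.
#' @return data.frame with columns `left`, `right`, `total` (Morgans) and
#'   `truncated`.
#' @export
simulate_segment_lengths <- function(n, g, region_morgans = NULL) {
  stopifnot(n >= 1, g > 0)
  left <- stats::rexp(n, rate = 2 * g)
  right <- stats::rexp(n, rate = 2 * g)
  truncated <- rep(FALSE, n)
  if (!is.null(region_morgans)) {
    truncated <- left > region_morgans[1] | right > region_morgans[2]
    left <- pmin(left, region_morgans[1])
    right <- pmin(right, region_morgans[2])
  }
  data.frame(left = left, right = right, total = left + right,
             truncated = truncated)
}

#' Simulate a carrier panel with a planted ancestral segment
#'
#' Emulates the data regime of an across-breed IBD scan: one ancestral
#' haplotype around a focal mutation, carried by heterozygous and
#' homozygous animals whose retained segments erode per
#' [simulate_segment_lengths()]; background haplotypes are drawn
#' marker-independently from per-marker background allele frequencies
#' (no background linkage disequilibrium — sufficient for the
#' opposing-homozygote logic, see the vignette). Defaults mirror the
#' published scan: 38 carriers (35 heterozygous, 3 homozygous), a control
#' group of the same size, ~9448 markers over ~1.17 Mb and a true age of
#' 565 generations.
#'
#' @param n_carriers total carriers (default 38).
#' @param n_hom how many carriers are homozygous for the focal mutation
#'   (their second haplotype is an independently eroded copy of the
#'   ancestral one; default 3).
#' @param n_controls non-carrier animals (default 38).
#' @param g true mutation age in generations (default 565).
#' @param n_markers marker count (default 9448).
#' @param spacing_bp physical distance between markers (default 124 bp,
#'   giving a ~1.17-Mb region).
#' @param cm_per_mb genetic map rate (default 1).
#' @param freq_range range of the per-marker background allele frequencies
#'   (drawn uniformly; default `c(0.1, 0.9)`).
#' @param region_start 1-based position of the first marker.
#' @return list with `reference` (a `reference_haplotype` built from the
#'   ancestral alleles, QUAL 999 at every marker), `geno_carriers` and
#'   `geno_controls` (dosage matrices, individuals x markers), `h1`/`h2`
#'   (phased carrier haplotypes, markers x carriers), `markers`,
#'   `focal_pos`, and `truth` (per-carrier segment bounds in bp and their
#'   intersection `c(start, end)`).
#' @export
simulate_carrier_panel <- function(n_carriers = 38L, n_hom = 3L,
                                   n_controls = 38L, g = 565,
                                   n_markers = 9448L, spacing_bp = 124,
                                   cm_per_mb = 1,
                                   freq_range = c(0.1, 0.9),
                                   region_start = 1L) {
  stopifnot(n_carriers >= 0L, n_hom <= n_carriers)
  pos <- as.integer(region_start + spacing_bp * (seq_len(n_markers) - 1L))
  focal_index <- as.integer(ceiling(n_markers / 2))
  focal_pos <- pos[focal_index]
  bp_per_morgan <- 1e8 / cm_per_mb
  f <- stats::runif(n_markers, freq_range[1], freq_range[2])
  ancestral <- as.integer(stats::rbinom(n_markers, 1L, f))
  background <- function(k) matrix(stats::rbinom(n_markers * k, 1L, f),
                                   nrow = n_markers)

  left_m <- (focal_pos - pos[1]) / bp_per_morgan
  right_m <- (pos[n_markers] - focal_pos) / bp_per_morgan
  seg <- if (n_carriers > 0L)
    simulate_segment_lengths(n_carriers + n_hom, g,
                             region_morgans = c(left_m, right_m))
  else data.frame(left = numeric(), right = numeric(),
                  total = numeric(), truncated = logical())
  bounds <- function(i) c(start = focal_pos - seg$left[i] * bp_per_morgan,
                          end = focal_pos + seg$right[i] * bp_per_morgan)
  paste_segment <- function(hap, b) {
    inside <- pos >= b["start"] & pos <= b["end"]
    hap[inside] <- ancestral[inside]
    hap
  }

  h1 <- background(n_carriers)
  h2 <- background(n_carriers)
  seg_bounds <- matrix(NA_real_, nrow = n_carriers, ncol = 2,
                       dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(n_carriers)) {
    b <- bounds(i)
    h1[, i] <- paste_segment(h1[, i], b)
    seg_bounds[i, ] <- b
    if (i <= n_hom) { # homozygous carriers: second eroded ancestral copy
      b2 <- bounds(n_carriers + i)
      h2[, i] <- paste_segment(h2[, i], b2)
      # an opposing homozygote needs BOTH alleles opposite: a homozygous
      # carrier is shielded over the union of its two retained segments
      seg_bounds[i, ] <- c(min(b["start"], b2["start"]),
                           max(b["end"], b2["end"]))
    }
  }
  geno_carriers <- t(h1 + h2)
  if (n_carriers > 0L)
    rownames(geno_carriers) <- paste0("carrier", seq_len(n_carriers))
  geno_controls <- if (n_controls > 0L) {
    gc <- t(background(n_controls) + background(n_controls))
    rownames(gc) <- paste0("control", seq_len(n_controls))
    gc
  } else {
    matrix(integer(), nrow = 0L, ncol = n_markers)
  }

  markers <- data.frame(chrom = "chr14", pos = pos,
                        qual = 999, stringsAsFactors = FALSE)
  markers$variant_id <- paste0("chr14:", pos)
  reference <- structure(list(markers = markers, allele = ancestral,
                              qual_min = 999),
                         class = "reference_haplotype")
  intersection <- if (n_carriers > 0L)
    c(start = max(seg_bounds[, "start"]), end = min(seg_bounds[, "end"]))
  else c(start = NA_real_, end = NA_real_)
  list(reference = reference, geno_carriers = geno_carriers,
       geno_controls = geno_controls, h1 = h1, h2 = h2,
       markers = markers, focal_pos = focal_pos,
       truth = list(segments = as.data.frame(seg_bounds),
                    intersection = intersection, g = g,
                    truncated = seg$truncated[seq_len(n_carriers)]))
}

#' Simulate random annotated variants for screen stress-testing
#'
#' Draws variants whose QUAL, MQ, missingness, consequence, SIFT score,
#' gene symbol, codon index and per-breed frequencies straddle every
#' threshold of the filter cascade, so that a random fixture exercises all
#' rules at once.
#'
#' @param n number of variants.
#' @param panel a [breed_panel()].
#' @param p_repeat fraction of variants placed inside the companion repeat
#'   interval (positions 1-based 10001..20000 on chr1).
#' @return list with `vs` (a [variant_set()]) and `repeats` (an
#'   [interval_set()]).
#' @export
simulate_random_variants <- function(n, panel, p_repeat = 0.1) {
  samples <- panel$map$sample_id
  ns <- length(samples)
  conseq_pool <- c("frameshift_variant", "stop_gained", "stop_lost",
                   "splice_acceptor_variant", "splice_donor_variant",
                   "initiator_codon_variant", "missense_variant",
                   "missense_variant", "synonymous_variant",
                   "intron_variant")
  in_repeat <- stats::runif(n) < p_repeat
  pos <- integer(n) # unique positions so variant ids stay distinct
  pos[in_repeat] <- sample(10001:20000, sum(in_repeat))
  pos[!in_repeat] <- sample(20001:200000, sum(!in_repeat))
  is_indel <- stats::runif(n) < 0.15
  variants <- data.frame(
    chrom = "chr1", pos = pos,
    ref = ifelse(is_indel, "AT", "A"),
    alt = "G",
    qual = sample(c(999, 500, 100, 31, 30, 29, 10), n, replace = TRUE),
    mq = sample(c(60, 59, 58, 50, NA), n, replace = TRUE,
                prob = c(0.4, 0.3, 0.1, 0.1, 0.1)),
    consequence = sample(conseq_pool, n, replace = TRUE),
    sift = NA_real_,
    gene = sample(c("GENEA", "GENEB", "GENEC", "ENSBTAG00000012345",
                    NA_character_), n, replace = TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.1, 0.1)),
    codon = sample(c(1L:5L, NA_integer_), n, replace = TRUE),
    stringsAsFactors = FALSE)
  mis <- variants$consequence == "missense_variant"
  variants$sift[mis] <- sample(c(0, 0, 0.01, 0.03, 0.2, NA), sum(mis),
                               replace = TRUE)
  # per-variant target frequency straddling the 5% threshold
  target_f <- sample(c(0, 0.01, 0.04, 0.05, 0.08, 0.2, 0.5), n,
                     replace = TRUE)
  geno <- matrix(stats::rbinom(n * ns, 2L, rep(target_f, ns)), nrow = n)
  # some singletons and missingness
  singleton <- stats::runif(n) < 0.1
  geno[singleton, ] <- 0L
  for (i in which(singleton)) geno[i, sample.int(ns, 1L)] <- 1L
  miss <- matrix(stats::runif(n * ns) <
                   rep(sample(c(0, 0.02, 0.05, 0.10), n, replace = TRUE), ns),
                 nrow = n)
  geno[miss] <- NA_integer_
  list(vs = variant_set(variants, geno, samples),
       repeats = interval_set("chr1", 10000, 20000))
}

# one planned variant per screen failure mode, plus clean passers
screen_fixture_modes <- c("pass", "low_qual", "bad_mq", "missing",
                          "singleton", "low_maf", "repeat_region",
                          "same_codon_a", "same_codon_b", "no_gene",
                          "non_candidate", "sift_above")

#' Emit a screen fixture: annotated VCF, breed map and repeat BED
#'
#' Writes a small fully-determined fixture in which each variant violates
#' one planned rule of the filter cascade (or none, for the clean passers),
#' together with its companion breed map and repeat track, and returns the
#' intended outcome of every variant. The panel holds `n_breeds` breeds of
#' `samples_per_breed` animals each.
#'
#' Note that a singleton allele also sits below the frequency threshold by
#' construction; the recorded failing rule follows the cascade's fixed
#' attribution order.
#'
#' @param dir output directory (created if needed).
#' @param n_pass number of clean passing variants (default 1, for the
#'   canonical 12-variant fixture).
#' @param n_breeds,samples_per_breed panel composition (default 3 x 25).
#' @return list with `vcf`, `breeds`, `bed` (paths) and `truth`
#'   (data.frame `variant_id`, `mode`, `intended_pass`, `fail_rule`).
#' @export
simulate_screen_vcf <- function(dir = tempfile("screenfix"), n_pass = 1L,
                                n_breeds = 3L, samples_per_breed = 25L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  breeds <- LETTERS[seq_len(n_breeds)]
  samples <- paste0(rep(breeds, each = samples_per_breed),
                    seq_len(samples_per_breed))
  panel <- breed_panel(samples, rep(breeds, each = samples_per_breed))
  ns <- length(samples)

  modes <- c(rep("pass", n_pass),
             screen_fixture_modes[screen_fixture_modes != "pass"])
  n <- length(modes)
  # genotype rows: default 5 het carriers in breed A (freq 0.1 there)
  geno <- matrix(0L, nrow = n, ncol = ns)
  for (i in seq_len(n)) geno[i, seq_len(5L)] <- 1L
  variants <- data.frame(
    chrom = "chr1", pos = 1000L + 100L * seq_len(n),
    ref = "A", alt = "G",
    qual = 999, mq = 60, consequence = "frameshift_variant",
    sift = NA_real_, gene = paste0("GENE", seq_len(n)),
    codon = NA_integer_, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    switch(modes[i],
      low_qual = { variants$qual[i] <- 30 },            # boundary: not > 30
      bad_mq = { variants$mq[i] <- 58 },
      missing = { geno[i, (ns - 3L):ns] <- NA_integer_ }, # 4/75 > 5%
      singleton = { geno[i, ] <- 0L; geno[i, 1L] <- 1L },
      low_maf = { geno[i, ] <- 0L; geno[i, 1:2] <- 1L },  # 2/50 = 4% max
      repeat_region = { variants$pos[i] <- 50005L },
      same_codon_a = { variants$consequence[i] <- "missense_variant"
                       variants$sift[i] <- 0
                       variants$gene[i] <- "SHAREDGENE"
                       variants$codon[i] <- 791L },
      same_codon_b = { variants$consequence[i] <- "missense_variant"
                       variants$sift[i] <- 0
                       variants$gene[i] <- "SHAREDGENE"
                       variants$codon[i] <- 791L },
      no_gene = { variants$gene[i] <- "ENSBTAG00000099999" },
      non_candidate = { variants$consequence[i] <- "synonymous_variant" },
      sift_above = { variants$consequence[i] <- "missense_variant"
                     variants$sift[i] <- 0.03 },
      pass = NULL)
  }
  vs <- variant_set(variants, geno, samples)

  fail_rule <- c(pass = NA_character_, low_qual = "site_quality",
                 bad_mq = "site_quality", missing = "site_quality",
                 singleton = "singleton", low_maf = "maf",
                 repeat_region = "repeat_region",
                 same_codon_a = "same_codon", same_codon_b = "same_codon",
                 no_gene = "gene_symbol",
                 non_candidate = "candidate_consequence",
                 sift_above = "candidate_consequence")[modes]
  truth <- data.frame(variant_id = vs$variants$variant_id, mode = modes,
                      intended_pass = modes == "pass",
                      fail_rule = unname(fail_rule),
                      stringsAsFactors = FALSE)

  vcf <- file.path(dir, "screen.vcf")
  write_vcf(vs, vcf)
  breeds_path <- file.path(dir, "breeds.tsv")
  utils::write.table(panel$map, breeds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- file.path(dir, "repeats.bed")
  writeLines("chr1\t50000\t50010\trepeat1", bed)
  list(vcf = vcf, breeds = breeds_path, bed = bed, truth = truth)
}

#' Simulate a phased birth-year cohort with a programmed frequency path
#'
#' Generates a cohort of animals born across a span of years whose focal
#' (Fs) allele frequency follows a programmed linear path, each allele
#' tagged by a 50-marker haplotype drawn from disjoint Fs and Wt haplotype
#' pools, with an optional fraction of shared haplotypes appearing on both
#' backgrounds (those end up undetermined in the status test). Defaults
#' emulate the published cohort: ~1375 AI bulls born 1975-2015 with a
#' decline from 40 to 27 %.
#'
#' @param years vector of birth years (default `1975:2015`).
#' @param n_per_year animals born per year (default 33).
#' @param freq_start,freq_end endpoints of the linear Fs-frequency path
#'   (defaults 0.40 and 0.27).
#' @param n_fs_haps,n_wt_haps sizes of the Fs- and Wt-tagged haplotype
#'   pools (defaults 5 and 20).
#' @param shared_frac probability that an allele draws its haplotype from a
#'   shared pool present on both backgrounds (default 0.04).
#' @param n_shared_haps size of the shared pool (default 2).
#' @param n_markers haplotype window size (default 50).
#' @return list with `hm` (a [haplotype_matrix()]), `meta` (data.frame
#'   `sample_id`, `breed`, `birth_year`, `focal_genotype`) and `truth`
#'   (`freq_by_year`, per-animal `genotype`, haplotype pool assignments).
#' @export
simulate_trajectory_cohort <- function(years = 1975:2015, n_per_year = 33L,
                                       freq_start = 0.40, freq_end = 0.27,
                                       n_fs_haps = 5L, n_wt_haps = 20L,
                                       shared_frac = 0.04,
                                       n_shared_haps = 2L,
                                       n_markers = 50L) {
  path <- seq(freq_start, freq_end, length.out = length(years))
  rand_hap <- function() stats::rbinom(n_markers, 1L, 0.5)
  # distinct pools: regenerate on collision
  pool <- list()
  while (length(pool) < n_fs_haps + n_wt_haps + n_shared_haps) {
    h <- rand_hap()
    key <- paste(h, collapse = "")
    if (!key %in% names(pool)) pool[[key]] <- h
  }
  pool_mat <- do.call(cbind, pool)
  fs_idx <- seq_len(n_fs_haps)
  wt_idx <- n_fs_haps + seq_len(n_wt_haps)
  sh_idx <- n_fs_haps + n_wt_haps + seq_len(n_shared_haps)

  n_total <- length(years) * n_per_year
  birth_year <- rep(years, each = n_per_year)
  p <- rep(path, each = n_per_year)
  allele1 <- stats::rbinom(n_total, 1L, p) # 1 = Fs
  allele2 <- stats::rbinom(n_total, 1L, p)
  draw_hap_idx <- function(is_fs) {
    shared <- stats::runif(length(is_fs)) < shared_frac
    idx <- integer(length(is_fs))
    idx[shared] <- sample(sh_idx, sum(shared), replace = TRUE)
    nfs <- !shared & is_fs == 1L
    idx[nfs] <- sample(fs_idx, sum(nfs), replace = TRUE)
    nwt <- !shared & is_fs == 0L
    idx[nwt] <- sample(wt_idx, sum(nwt), replace = TRUE)
    idx
  }
  i1 <- draw_hap_idx(allele1)
  i2 <- draw_hap_idx(allele2)
  h1 <- pool_mat[, i1, drop = FALSE]
  h2 <- pool_mat[, i2, drop = FALSE]
  samples <- sprintf("bull%04d", seq_len(n_total))
  markers <- data.frame(chrom = "chr14",
                        pos = 22587081L + 1000L * (seq_len(n_markers) - 1L),
                        stringsAsFactors = FALSE)
  hm <- haplotype_matrix(markers, h1, h2, samples)
  genotype <- c("Wt/Wt", "Fs/Wt", "Fs/Fs")[allele1 + allele2 + 1L]
  meta <- data.frame(sample_id = samples, breed = "Normande",
                     birth_year = birth_year, focal_genotype = genotype,
                     stringsAsFactors = FALSE)
  list(hm = hm, meta = meta,
       truth = list(freq_by_year = stats::setNames(path, years),
                    genotype = genotype,
                    fs_haps = fs_idx, wt_haps = wt_idx, shared = sh_idx,
                    hap1_pool = i1, hap2_pool = i2))
}
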