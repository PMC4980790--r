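#' Configuration of the deleterious-variant filter cascade
#'
#' Thresholds for selecting non-rare putative loss-of-function variants from
#' a multi-breed panel. Defaults reproduce the published cascade: calling
#' quality QUAL strictly above 30; mapping quality MQ of 59 or 60; fewer than
#' 5 % of animals with a missing genotype; a loss-of-function consequence or
#' a missense with SIFT score 0; allele frequency of at least 5 % in at
#' least one breed with a minimum of 20 genotyped animals; alleles observed
#' only once discarded; a known gene symbol required.
#'
#' @param qual_min QUAL threshold, strict `>` (default 30).
#' @param mq_allowed admissible MQ values (default `c(59, 60)`).
#' @param missing_max maximum missing-genotype fraction, strict `<`
#'   (default 0.05).
#' @param maf_min minimum within-breed alternate-allele frequency
#'   (default 0.05, compared with `>=`).
#' @param maf_strict if `TRUE` the frequency comparison is strict `>`
#'   instead of `>=`.
#' @param breed_min_n minimum number of genotyped animals for a breed to
#'   count towards the frequency rule (default 20).
#' @param lof_consequences consequence terms accepted as loss-of-function
#'   irrespective of SIFT.
#' @param sift_max_for_missense maximum SIFT score for a missense variant to
#'   be retained (default 0: only the most damaging predictions).
#' @param require_gene_symbol drop variants without an official gene symbol
#'   (default `TRUE`).
#' @param ensembl_id_pattern regex; a gene field matching it (a bare
#'   Ensembl identifier) does not count as an official symbol.
#' @param singleton_exclusion drop variants whose alternate allele is seen
#'   exactly once across the whole panel (default `TRUE`).
#' @param missing_per_breed if `TRUE` the missingness rule is applied within
#'   each breed instead of over all samples.
#' @return object of class `screen_config` (a named list).
#' @export
screen_config <- function(qual_min = 30,
                          mq_allowed = c(59, 60),
                          missing_max = 0.05,
                          maf_min = 0.05,
                          maf_strict = FALSE,
                          breed_min_n = 20L,
                          lof_consequences = c("initiator_codon_variant",
                                               "start_lost",
                                               "splice_acceptor_variant",
                                               "splice_donor_variant",
                                               "frameshift_variant",
                                               "stop_lost",
                                               "stop_gained"),
                          sift_max_for_missense = 0,
                          require_gene_symbol = TRUE,
                          ensembl_id_pattern = "^ENS[A-Z]*G[0-9]+$",
                          singleton_exclusion = TRUE,
                          missing_per_breed = FALSE) {
  stopifnot(missing_max >= 0, missing_max <= 1,
            maf_min >= 0, maf_min <= 1, breed_min_n >= 1)
  structure(list(qual_min = qual_min, mq_allowed = mq_allowed,
                 missing_max = missing_max, maf_min = maf_min,
                 maf_strict = maf_strict,
                 breed_min_n = as.integer(breed_min_n),
                 lof_consequences = lof_consequences,
                 sift_max_for_missense = sift_max_for_missense,
                 require_gene_symbol = require_gene_symbol,
                 ensembl_id_pattern = ensembl_id_pattern,
                 singleton_exclusion = singleton_exclusion,
                 missing_per_breed = missing_per_breed),
            class = "screen_config")
}

#' Candidate-consequence test
#'
#' A variant is a candidate when its consequence is loss-of-function
#' (initiator codon, splice acceptor/donor, frameshift, stop lost/gained)
#' or it is a missense with a SIFT score at or below the configured
#' threshold. A missense with no SIFT annotation is not a candidate.
#'
#' @param consequence character vector of consequence terms.
#' @param sift numeric vector of SIFT scores (`NA` when absent).
#' @param cfg a [screen_config()].
#' @return logical vector.
#' @export
is_candidate_consequence <- function(consequence, sift = NA_real_,
                                     cfg = screen_config()) {
  if (inherits(consequence, "variant_set")) {
    sift <- consequence$variants$sift
    consequence <- consequence$variants$consequence
  }
  lof <- !is.na(consequence) & consequence %in% cfg$lof_consequences
  mis <- !is.na(consequence) & consequence == "missense_variant" &
    !is.na(sift) & sift <= cfg$sift_max_for_missense
  lof | mis
}

#' Site-quality test
#'
#' True iff QUAL is strictly above the threshold, MQ is one of the admitted
#' values (an absent MQ fails, conservatively) and the missing-genotype
#' fraction is strictly below the maximum.
#'
#' @param vs a [variant_set()].
#' @param cfg a [screen_config()].
#' @param panel optional [breed_panel()]; needed only when
#'   `cfg$missing_per_breed` is set, in which case the missingness rule must
#'   hold in every breed.
#' @return logical vector, one entry per variant.
#' @export
passes_site_quality <- function(vs, cfg = screen_config(), panel = NULL) {
  v <- vs$variants
  qual_ok <- !is.na(v$qual) & v$qual > cfg$qual_min
  mq_ok <- !is.na(v$mq) & v$mq %in% cfg$mq_allowed
  if (isTRUE(cfg$missing_per_breed)) {
    if (is.null(panel)) stop("missing_per_breed requires a breed panel")
    miss_ok <- rep(TRUE, nrow(v))
    for (b in names(panel$counts)) {
      cols <- panel$map$sample_id[panel$map$breed == b]
      frac <- rowMeans(is.na(vs$geno[, cols, drop = FALSE]))
      miss_ok <- miss_ok & frac < cfg$missing_max
    }
  } else {
    miss_ok <- rowMeans(is.na(vs$geno)) < cfg$missing_max
  }
  unname(qual_ok & mq_ok & miss_ok)
}

#' Per-breed allele counts and frequencies
#'
#' For each variant and breed: number of genotyped (non-missing) animals,
#' alternate-allele count and frequency `alt / (2 * genotyped)`. Breeds with
#' no genotyped animal at a variant are omitted for that variant.
#'
#' @param vs a [variant_set()].
#' @param panel a [breed_panel()]; every panel sample must be genotyped in
#'   `vs`.
#' @return data.frame with columns `variant_id`, `breed`, `n_genotyped`,
#'   `alt_count`, `freq`.
#' @export
per_breed_allele_stats <- function(vs, panel) {
  missing_samples <- setdiff(panel$map$sample_id, vs$samples)
  if (length(missing_samples))
    stop("panel samples absent from variant set: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  out <- lapply(names(panel$counts), function(b) {
    cols <- panel$map$sample_id[panel$map$breed == b]
    g <- vs$geno[, cols, drop = FALSE]
    n_gt <- rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    data.frame(variant_id = vs$variants$variant_id, breed = b,
               n_genotyped = n_gt, alt_count = alt,
               freq = ifelse(n_gt > 0, alt / (2 * n_gt), NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_genotyped > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Same-codon substitution conflicts
#'
#' Adjacent substitutions within one codon are mis-annotated when considered
#' independently; all pairs of distinct SNVs sharing a (gene, codon) are
#' flagged and both members excluded. Indels and variants without a codon
#' index are not considered.
#'
#' @param vs a [variant_set()].
#' @return list with `pairs` (data.frame `id_a`, `id_b`) and `excluded`
#'   (character vector of variant ids).
#' @export
same_codon_conflicts <- function(vs) {
  v <- vs$variants
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    !is.na(v$gene) & !is.na(v$codon)
  key <- paste(v$gene, v$codon, sep = "@")
  pairs <- NULL
  for (k in unique(key[snv])) {
    ids <- v$variant_id[snv & key == k]
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      pairs <- rbind(pairs, data.frame(id_a = cmb[1L, ], id_b = cmb[2L, ],
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE)
  list(pairs = pairs, excluded = unique(c(pairs$id_a, pairs$id_b)))
}

screen_rules <- c("candidate_consequence", "site_quality", "singleton",
                  "maf", "repeat_region", "same_codon", "gene_symbol")

#' Apply the full deleterious-variant filter cascade
#'
#' Rules are evaluated in a fixed order — candidate consequence, site
#' quality, singleton exclusion, within-breed frequency, repeat-region
#' exclusion, same-codon conflict, gene-symbol requirement — and each
#' failing variant is attributed to its first failing rule. The order
#' affects only the attribution, never the final pass set.
#'
#' @param vs a [variant_set()] (biallelic by construction).
#' @param panel a [breed_panel()].
#' @param repeats optional [interval_set()] of repeat regions; a variant
#'   fails when its position (for indels, the full REF span) overlaps one.
#' @param cfg a [screen_config()].
#' @return object of class `screen_report`: list with `results` (per-variant
#'   data.frame: `variant_id`, `pass`, `first_fail`, `n_breeds_shared`),
#'   `removed` (named integer, per-rule removals), `n_pass`, `n_genes`,
#'   `freq` (the [per_breed_allele_stats()] table), and `cfg`.
#' @export
apply_screen <- function(vs, panel, repeats = NULL, cfg = screen_config()) {
  if (!inherits(panel, "breed_panel") || sum(panel$counts) == 0L)
    stop("apply_screen needs a non-empty breed panel")
  v <- vs$variants
  n <- nrow(v)
  freq <- per_breed_allele_stats(vs, panel)

  ok <- matrix(TRUE, nrow = n, ncol = length(screen_rules),
               dimnames = list(v$variant_id, screen_rules))
  ok[, "candidate_consequence"] <- is_candidate_consequence(
    v$consequence, v$sift, cfg)
  ok[, "site_quality"] <- passes_site_quality(vs, cfg, panel)
  total_alt <- rowSums(vs$geno, na.rm = TRUE)
  ok[, "singleton"] <- if (cfg$singleton_exclusion) total_alt >= 2 else TRUE

  # frequency rule: >= maf_min in at least one breed with enough genotyped
  # animals (eligibility counted on genotyped animals at the site)
  hit <- freq$n_genotyped >= cfg$breed_min_n &
    (if (cfg$maf_strict) freq$freq > cfg$maf_min else freq$freq >= cfg$maf_min)
  n_shared <- tapply(hit, factor(freq$variant_id, levels = v$variant_id), sum)
  n_shared[is.na(n_shared)] <- 0L
  ok[, "maf"] <- as.integer(n_shared) >= 1L

  if (!is.null(repeats) && nrow(repeats) > 0L) {
    span_end <- v$pos + nchar(v$ref) - 1L
    ok[, "repeat_region"] <- !in_intervals(repeats, v$chrom, v$pos, span_end)
  }
  ok[, "same_codon"] <- !(v$variant_id %in% same_codon_conflicts(vs)$excluded)
  if (cfg$require_gene_symbol) {
    has_symbol <- !is.na(v$gene) & v$gene != "" & v$gene != "." &
      !grepl(cfg$ensembl_id_pattern, v$gene)
    ok[, "gene_symbol"] <- has_symbol
  }

  pass <- rowSums(!ok) == 0L
  first_fail <- rep(NA_character_, n)
  for (i in which(!pass))
    first_fail[i] <- screen_rules[which(!ok[i, ])[1L]]
  removed <- stats::setNames(
    vapply(screen_rules, function(r) sum(first_fail == r, na.rm = TRUE),
           integer(1)), screen_rules)

  results <- data.frame(variant_id = v$variant_id, pass = pass,
                        first_fail = first_fail,
                        n_breeds_shared = as.integer(n_shared),
                        stringsAsFactors = FALSE)
  structure(list(results = results, removed = removed,
                 n_pass = sum(pass),
                 n_genes = length(unique(v$gene[pass & !is.na(v$gene)])),
                 freq = freq, panel = panel, cfg = cfg,
                 variants = v),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report: ", nrow(x$results), " variants in, ",
      x$n_pass, " pass (", x$n_genes, " genes)\n", sep = "")
  cat("removed by first failing rule:\n")
  for (r in names(x$removed))
    if (x$removed[[r]] > 0)
      cat(sprintf("  %-22s %d\n", r, x$removed[[r]]))
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  sh <- breed_sharing_summary(object)
  cat("passing variants shared by >1 breed: ",
      format(100 * sh$frac_shared_multi, digits = 3), "%; by all breeds: ",
      format(100 * sh$frac_shared_all, digits = 3), "%\n", sep = "")
  invisible(sh)
}

#' Breed-sharing summary of the passing variants
#'
#' For each passing variant, the number of breeds in which it segregates at
#' or above the frequency threshold (with enough genotyped animals); per
#' breed, the histogram of that sharing count over the breed's own passing
#' variants; and the overall fractions shared by more than one breed and by
#' all eligible breeds.
#'
#' @param report a `screen_report` from [apply_screen()].
#' @return list with `histogram` (breeds x sharing-count matrix),
#'   `frac_shared_multi`, `frac_shared_all`, `n_breeds_shared` (named
#'   integer vector over passing variants).
#' @export
breed_sharing_summary <- function(report) {
  res <- report$results[report$results$pass, , drop = FALSE]
  cfg <- report$cfg
  freq <- report$freq
  breeds <- names(report$panel$counts)
  n_eligible <- sum(report$panel$eligible)
  shared <- stats::setNames(res$n_breeds_shared, res$variant_id)
  maxk <- max(1L, shared, na.rm = TRUE)
  histogram <- matrix(0L, nrow = length(breeds), ncol = maxk,
                      dimnames = list(breeds, as.character(seq_len(maxk))))
  hit <- freq$n_genotyped >= cfg$breed_min_n &
    (if (cfg$maf_strict) freq$freq > cfg$maf_min else freq$freq >= cfg$maf_min)
  for (b in breeds) {
    ids <- freq$variant_id[hit & freq$breed == b]
    ids <- intersect(ids, res$variant_id)
    if (length(ids))
      for (k in shared[ids]) histogram[b, k] <- histogram[b, k] + 1L
  }
  list(histogram = histogram,
       frac_shared_multi = if (nrow(res)) mean(shared > 1) else NA_real_,
       frac_shared_all = if (nrow(res)) mean(shared == n_eligible) else NA_real_,
       n_breeds_shared = shared)
}
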