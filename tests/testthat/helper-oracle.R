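# Independent oracles, written as plain per-variant loops so they share no
# code path with the vectorised implementations they check.

oracle_screen_pass <- function(vs, panel, repeats = NULL,
                               cfg = screen_config()) {
  v <- vs$variants
  g <- vs$geno
  lof <- cfg$lof_consequences
  pass <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    cons <- v$consequence[i]
    ok_cons <- (!is.na(cons) && cons %in% lof) ||
      (!is.na(cons) && cons == "missense_variant" && !is.na(v$sift[i]) &&
         v$sift[i] <= cfg$sift_max_for_missense)

    ok_qual <- !is.na(v$qual[i]) && v$qual[i] > cfg$qual_min &&
      !is.na(v$mq[i]) && v$mq[i] %in% cfg$mq_allowed &&
      mean(is.na(g[i, ])) < cfg$missing_max

    ok_singleton <- !cfg$singleton_exclusion ||
      sum(g[i, ], na.rm = TRUE) >= 2

    ok_maf <- FALSE
    for (b in unique(panel$map$breed)) {
      cols <- panel$map$sample_id[panel$map$breed == b]
      gb <- g[i, cols]
      n_gt <- sum(!is.na(gb))
      if (n_gt < cfg$breed_min_n) next
      f <- sum(gb, na.rm = TRUE) / (2 * n_gt)
      hit <- if (cfg$maf_strict) f > cfg$maf_min else f >= cfg$maf_min
      if (hit) ok_maf <- TRUE
    }

    ok_repeat <- TRUE
    if (!is.null(repeats) && nrow(repeats) > 0) {
      lo <- v$pos[i]
      hi <- v$pos[i] + nchar(v$ref[i]) - 1
      for (k in seq_len(nrow(repeats))) {
        if (repeats$chrom[k] == v$chrom[i] &&
            lo <= repeats$end[k] && hi >= repeats$start[k] + 1)
          ok_repeat <- FALSE
      }
    }

    ok_codon <- TRUE
    if (nchar(v$ref[i]) == 1 && nchar(v$alt[i]) == 1 &&
        !is.na(v$gene[i]) && !is.na(v$codon[i])) {
      for (j in seq_len(nrow(v))) {
        if (j == i) next
        if (nchar(v$ref[j]) == 1 && nchar(v$alt[j]) == 1 &&
            !is.na(v$gene[j]) && !is.na(v$codon[j]) &&
            v$gene[j] == v$gene[i] && v$codon[j] == v$codon[i])
          ok_codon <- FALSE
      }
    }

    ok_gene <- !cfg$require_gene_symbol ||
      (!is.na(v$gene[i]) && v$gene[i] != "" && v$gene[i] != "." &&
         !grepl(cfg$ensembl_id_pattern, v$gene[i]))

    pass[i] <- ok_cons && ok_qual && ok_singleton && ok_maf && ok_repeat &&
      ok_codon && ok_gene
  }
  pass
}

# Pearson statistic written out longhand
pearson_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# margin-preserving Monte Carlo null for the independence test
perm_chisq_p <- function(tab, n_shuffles = 1e5) {
  obs <- pearson_stat(tab)
  sims <- r2dtable(n_shuffles, rowSums(tab), colSums(tab))
  hits <- vapply(sims, function(s) pearson_stat(s) >= obs - 1e-12,
                 logical(1))
  mean(hits)
}
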