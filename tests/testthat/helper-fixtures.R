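# Hand-written file fixtures, built in code at test time.

# 3 biallelic records, 4 samples, one missing genotype; plain INFO keys.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf"),
                              extra_lines = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"csq\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"sift\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"codon\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("chr14", "100", ".", "A", "G", "999", "PASS",
          "MQ=60;CONSEQ=frameshift_variant;GENE=RP1", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("chr14", "250", ".", "C", "T", "45.5", "PASS",
          "MQ=59;CONSEQ=missense_variant;SIFT=0;GENE=GENEX;CODON=12", "GT",
          "0/1", "0/0", "0/0", "0/1", sep = "\t"),
    paste("chr14", "900", ".", "CT", "C", "30", "PASS",
          "MQ=58;CONSEQ=synonymous_variant", "GT",
          "0/0", "0/0", "0/1", "0/0", sep = "\t"),
    extra_lines)
  writeLines(lines, path)
  path
}

triallelic_line <- function() {
  paste("chr14", "500", ".", "A", "G,T", "999", "PASS",
        "MQ=60;CONSEQ=missense_variant", "GT",
        "0/1", "0/2", "0/0", "1/2", sep = "\t")
}

write_breed_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small in-code variant_set builder for rule-level tests
make_vs <- function(variants, geno, samples = paste0("s", seq_len(ncol(geno)))) {
  variant_set(variants, geno, samples)
}

# a 10-marker, 3-sample phased haplotype matrix
fixture_hm <- function(n_markers = 10L, n_samples = 3L, seed = 11) {
  set.seed(seed)
  markers <- data.frame(chrom = "chr14",
                        pos = seq(100L, by = 50L, length.out = n_markers))
  h <- function() matrix(rbinom(n_markers * n_samples, 1, 0.5),
                         nrow = n_markers)
  haplotype_matrix(markers, h(), h(), paste0("a", seq_len(n_samples)))
}

# hand-constructed window_profile for run-finding tests
make_profile <- function(n_flagged, anchor_pos = seq_along(n_flagged) * 100,
                         chrom = "chr14") {
  structure(data.frame(window_start = seq_along(n_flagged),
                       anchor_index = seq_along(n_flagged),
                       anchor_pos = anchor_pos, n_flagged = n_flagged),
            class = c("window_profile", "data.frame"),
            window_size = 100L, threshold = 0.05,
            n_individuals = max(n_flagged, 1L), chrom = chrom)
}
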