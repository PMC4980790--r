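#' Variant set: biallelic variants with site metadata and genotype dosages
#'
#' The central container of the screening pipeline. Holds one row per
#' biallelic variant (position, alleles, calling quality `qual`, mapping
#' quality `mq`, functional `consequence`, SIFT score, gene symbol, codon
#' index) together with an integer matrix of per-sample alternate-allele
#' dosages (0, 1, 2, or `NA` for a missing genotype).
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `mq`, `consequence`, `sift`, `gene`, `codon`. Optional columns
#'   are filled with `NA` when absent.
#' @param geno integer matrix, one row per variant, one column per sample;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers, one per genotype
#'   column.
#' @return An object of class `variant_set`: a list with elements
#'   `variants`, `geno` and `samples`. Row names of `geno` and
#'   `variants$variant_id` hold a `chrom:pos_ref_alt` identifier.
#' @export
variant_set <- function(variants, geno, samples) {
  stopifnot(is.data.frame(variants))
  needed <- c("chrom", "pos", "ref", "alt", "qual", "mq",
              "consequence", "sift", "gene", "codon")
  for (col in setdiff(needed, names(variants))) variants[[col]] <- NA
  variants <- variants[needed]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    stop("multi-allelic ALT found; variant_set holds biallelic records only")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants))
    stop("geno must have one row per variant")
  if (ncol(geno) != length(samples))
    stop("geno must have one column per sample (",
         length(samples), " samples, ", ncol(geno), " columns)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  variants$variant_id <- if (nrow(variants) > 0L)
    paste0(variants$chrom, ":", variants$pos, "_",
           variants$ref, "_", variants$alt) else character(0)
  rownames(geno) <- variants$variant_id
  colnames(geno) <- samples
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno,
                 samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set: ", nrow(x$variants), " biallelic variants x ",
      length(x$samples), " samples\n", sep = "")
  nm <- sum(is.na(x$geno))
  cat("  missing genotypes: ", nm, " (",
      format(100 * nm / length(x$geno), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Number of variants / samples in a variant_set
#' @param vs a `variant_set`
#' @return integer count
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' @rdname n_variants
#' @export
n_samples <- function(vs) length(vs$samples)

# "chr:start-end" -> list(chrom, start, end)
parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region '", region, "'; expected chrom:start-end")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# GT strings ("0/1", "0|1", ".", "./.") -> alt-allele dosage with NA sentinel.
gt_to_dosage <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
  out
}

#' Read an annotated VCF into a variant_set
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) keeping biallelic records. Site
#' annotations are taken from INFO keys whose names are configurable, so the
#' screen logic stays independent of any particular annotation dialect; the
#' defaults match the plain-key dialect written by [write_vcf()] and
#' [simulate_screen_vcf()].
#'
#' @param path path to a VCF file (plain text or gzip).
#' @param region optional `"chrom:start-end"` string; only records whose
#'   POS falls inside the (1-based, inclusive) range are returned.
#' @param info_keys named list mapping the fields `mq`, `consequence`,
#'   `sift`, `gene`, `codon` to INFO keys.
#' @param multiallelic `"skip"` (default) drops records with more than one
#'   ALT allele and records the count in attribute `n_multiallelic_skipped`;
#'   `"error"` aborts on the first such record.
#' @return a [variant_set()]; attribute `n_multiallelic_skipped` gives the
#'   number of multi-allelic records dropped.
#' @export
read_vcf <- function(path, region = NULL,
                     info_keys = list(mq = "MQ", consequence = "CONSEQ",
                                      sift = "SIFT", gene = "GENE",
                                      codon = "CODON"),
                     multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L)
    stop("VCF has no genotype (GT) columns: ", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!grepl("GT", fmt)))
    stop("records without a GT field in FORMAT: ", path)

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    if (multiallelic == "error")
      stop(n_multi, " multi-allelic record(s) in ", path)
    message("read_vcf: skipped ", n_multi, " multi-allelic record(s)")
  }

  keep <- !multi
  if (!is.null(region)) {
    rg <- parse_region(region)
    pos <- as.integer(fix[, "POS"])
    keep <- keep & fix[, "CHROM"] == rg$chrom & pos >= rg$start & pos <= rg$end
  }

  info_num <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    suppressWarnings(as.numeric(v))
  }
  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    ifelse(is.na(v) | v == "." | v == "", NA_character_, v)
  }

  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    mq = info_num(info_keys$mq),
    consequence = info_chr(info_keys$consequence),
    sift = info_num(info_keys$sift),
    gene = info_chr(info_keys$gene),
    codon = suppressWarnings(as.integer(info_num(info_keys$codon))),
    stringsAsFactors = FALSE
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  geno <- matrix(gt_to_dosage(as.vector(gt)), nrow = nrow(gt))

  variants <- variants[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  vs <- variant_set(variants, geno, samples)
  attr(vs, "n_multiallelic_skipped") <- n_multi
  vs
}

#' Write a variant_set to a plain-text VCF
#'
#' Emits VCF 4.2 with QUAL in the QUAL column and the remaining site
#' annotations as plain INFO keys (`MQ`, `CONSEQ`, `SIFT`, `GENE`, `CODON`),
#' genotypes as unphased GT. [read_vcf()] round-trips this dialect.
#'
#' @param vs a [variant_set()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  v <- vs$variants
  info <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    kv <- c(
      if (!is.na(v$mq[i])) paste0("MQ=", format(v$mq[i])),
      if (!is.na(v$consequence[i])) paste0("CONSEQ=", v$consequence[i]),
      if (!is.na(v$sift[i])) paste0("SIFT=", format(v$sift[i])),
      if (!is.na(v$gene[i])) paste0("GENE=", v$gene[i]),
      if (!is.na(v$codon[i])) paste0("CODON=", v$codon[i])
    )
    info[i] <- if (length(kv)) paste(kv, collapse = ";") else "."
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L], nrow = nrow(vs$geno))
  gt[is.na(vs$geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"Codon index\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )
  qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", info, "GT",
                sep = "\t")
  if (nrow(gt) > 0L)
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
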