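#' Breed panel: sample-to-breed assignment with eligibility counts
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param breed character vector of breed labels, parallel to `sample_id`.
#' @param breed_min_n minimum number of animals for a breed to be eligible
#'   for the allele-frequency screen (default 20).
#' @return object of class `breed_panel`: list with `map` (data.frame),
#'   `counts` (named integer), `eligible` (named logical) and `breed_min_n`.
#' @export
breed_panel <- function(sample_id, breed, breed_min_n = 20L) {
  sample_id <- as.character(sample_id)
  breed <- as.character(breed)
  if (length(sample_id) != length(breed))
    stop("sample_id and breed must have equal length")
  if (length(sample_id) == 0L) stop("empty breed panel")
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(breed) || any(breed == ""))
    stop("every sample must have exactly one breed label")
  counts <- table(breed)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(map = data.frame(sample_id = sample_id, breed = breed,
                                  stringsAsFactors = FALSE),
                 counts = counts,
                 eligible = counts >= breed_min_n,
                 breed_min_n = as.integer(breed_min_n)),
            class = "breed_panel")
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("breed_panel:", sum(x$counts), "samples in", length(x$counts),
      "breed(s)\n")
  for (b in names(x$counts))
    cat(sprintf("  %-20s n = %4d  %s\n", b, x$counts[[b]],
                if (x$eligible[[b]]) "eligible" else
                  paste0("(< ", x$breed_min_n, ", not eligible)")))
  invisible(x)
}

#' Read a sample-to-breed map from a two-column TSV
#'
#' @param path TSV with a header line and columns `sample_id`, `breed`.
#' @inheritParams breed_panel
#' @return a [breed_panel()]
#' @export
read_breed_map <- function(path, breed_min_n = 20L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty breed map: ", path)
  if (!all(c("sample_id", "breed") %in% names(df)))
    stop("breed map needs columns sample_id, breed: ", path)
  breed_panel(df$sample_id, df$breed, breed_min_n = breed_min_n)
}

#' Sorted, merged interval set (0-based half-open)
#'
#' Container for genomic interval tracks such as a repeat-masker BED.
#' Overlapping or bookended intervals are merged (via \pkg{IRanges}).
#'
#' @param chrom,start,end parallel vectors; `start`/`end` use the BED
#'   convention (0-based half-open, `start < end`).
#' @return class `interval_set`: data.frame with columns `chrom`, `start`,
#'   `end`, sorted by chrom then start, non-overlapping.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  if (length(chrom) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end))
    stop("interval start must be < end (0-based half-open)")
  pieces <- lapply(split(seq_along(chrom), as.character(chrom)), function(i) {
    # IRanges are 1-based closed; shift half-open [s,e) to [s+1, e]
    r <- IRanges::reduce(IRanges::IRanges(start = start[i] + 1, end = end[i]))
    data.frame(chrom = chrom[i][1],
               start = IRanges::start(r) - 1,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Read a repeat track from a BED file
#'
#' @param path BED file (>= 3 columns, no header).
#' @return an [interval_set()] with overlapping intervals merged; an empty
#'   file yields an empty set.
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(interval_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("BED lines need >= 3 columns: ", path)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  interval_set(chrom, start, end)
}

#' Convert a 1-based VCF position to the 0-based half-open coordinate system
#'
#' The single reconciliation point between the two conventions: a 1-bp BED
#' interval `[k, k+1)` contains exactly VCF position `k+1`.
#'
#' @param pos 1-based position(s)
#' @return 0-based coordinate(s)
#' @export
pos_to_zero_based <- function(pos) as.numeric(pos) - 1

#' Test whether 1-based positions fall inside an interval set
#'
#' @param iv an [interval_set()]
#' @param chrom,pos parallel vectors of chromosome labels and 1-based
#'   positions (VCF convention)
#' @param span_end optional 1-based inclusive end positions (e.g. end of an
#'   indel REF span); a position-range overlaps if any base falls inside.
#' @return logical vector
#' @export
in_intervals <- function(iv, chrom, pos, span_end = pos) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  q0 <- pos_to_zero_based(pos)          # first base, 0-based
  q1 <- pos_to_zero_based(span_end) + 1 # past-the-end
  out <- logical(length(pos))
  for (cc in unique(as.character(chrom))) {
    qi <- which(chrom == cc)
    ti <- iv$chrom == cc
    if (!any(ti)) next
    s <- iv$start[ti]; e <- iv$end[ti]
    out[qi] <- vapply(qi, function(j) any(q0[j] < e & q1[j] > s), logical(1))
  }
  out
}

#' Phased haplotype matrix
#'
#' Ordered markers plus the two phased allele sequences of each sample,
#' alleles coded 0/1 with `NA` for missing.
#'
#' @param markers data.frame with columns `chrom`, `pos` and optionally `id`;
#'   positions must be strictly increasing within chromosome.
#' @param h1,h2 integer matrices (markers x samples) holding the first and
#'   second haplotype of each sample.
#' @param samples character vector of sample ids.
#' @return class `haplotype_matrix`: list(markers, h1, h2, samples).
#' @export
haplotype_matrix <- function(markers, h1, h2, samples) {
  stopifnot(is.data.frame(markers))
  if (is.null(markers$id)) markers$id <- paste0(markers$chrom, ":", markers$pos)
  markers$pos <- as.integer(markers$pos)
  for (cc in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == cc]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chrom ", cc)
  }
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (nrow(h1) != nrow(markers) || nrow(h2) != nrow(markers))
    stop("haplotypes must have one row per marker")
  if (ncol(h1) != length(samples) || ncol(h2) != length(samples))
    stop("haplotypes must have one column per sample")
  ok <- function(h) all(is.na(h) | h %in% c(0L, 1L))
  if (!ok(h1) || !ok(h2)) stop("alleles must be coded 0, 1 or NA")
  colnames(h1) <- colnames(h2) <- samples
  structure(list(markers = markers[c("chrom", "pos", "id")],
                 h1 = h1, h2 = h2, samples = as.character(samples)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", nrow(x$markers), " markers x ",
      length(x$samples), " samples (2 phased haplotypes each)\n", sep = "")
  invisible(x)
}

#' Read phased haplotypes from a phased VCF or a TSV dialect
#'
#' The VCF dialect requires every genotype to use the `|` phase separator;
#' an unphased genotype is an error naming the sample and site. The TSV
#' dialect has columns `chrom`, `pos`, `id` followed by two columns
#' `<sample>_1`, `<sample>_2` per sample (as written by
#' [write_phased_haplotypes()]). The dialect is sniffed from the first line.
#'
#' @param path input file
#' @return a [haplotype_matrix()]; marker order is file order.
#' @export
read_phased_haplotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt)
    unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
    if (any(unphased)) {
      w <- which(unphased, arr.ind = TRUE)[1L, ]
      stop("unphased genotype for sample ", samples[w[2L]], " at ",
           vcf@fix[w[1L], "CHROM"], ":", vcf@fix[w[1L], "POS"])
    }
    allele <- function(k) {
      a <- substr(gt, k, k)
      a[a == "." | a == "" | is.na(gt)] <- NA
      matrix(as.integer(a), nrow = nrow(gt))
    }
    markers <- data.frame(chrom = vcf@fix[, "CHROM"],
                          pos = as.integer(vcf@fix[, "POS"]),
                          id = ifelse(is.na(vcf@fix[, "ID"]) |
                                        vcf@fix[, "ID"] == ".",
                                      NA, vcf@fix[, "ID"]),
                          stringsAsFactors = FALSE)
    return(haplotype_matrix(markers, allele(1L), allele(3L), samples))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "pos", "id") %in% names(df)))
    stop("TSV haplotype dialect needs columns chrom, pos, id: ", path)
  hap_cols <- setdiff(names(df), c("chrom", "pos", "id"))
  s1 <- grep("_1$", hap_cols, value = TRUE)
  samples <- sub("_1$", "", s1)
  if (!all(paste0(samples, "_2") %in% hap_cols) ||
      length(hap_cols) != 2L * length(samples))
    stop("TSV haplotype dialect needs paired <sample>_1/<sample>_2 columns")
  h1 <- as.matrix(df[paste0(samples, "_1")])
  h2 <- as.matrix(df[paste0(samples, "_2")])
  haplotype_matrix(df[c("chrom", "pos", "id")], h1, h2, samples)
}

#' Write phased haplotypes to the TSV dialect
#'
#' @param hm a [haplotype_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phased_haplotypes <- function(hm, path) {
  out <- hm$markers
  for (i in seq_along(hm$samples)) {
    out[[paste0(hm$samples[i], "_1")]] <- hm$h1[, i]
    out[[paste0(hm$samples[i], "_2")]] <- hm$h2[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
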