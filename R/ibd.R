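#' Build a reference haplotype from a homozygous animal
#'
#' Inside a region where a chosen animal (typically a homozygous mutant) is
#' identical by descent on both chromosomes, its homozygous genotypes at
#' top-quality sites define a reference haplotype against which other
#' animals can be compared without phasing.
#'
#' @param vs a [variant_set()] containing the reference animal.
#' @param ref_sample sample id of the reference animal.
#' @param region optional `"chrom:start-end"` restriction.
#' @param qual_min minimum QUAL for a marker to be retained (default 999,
#'   the cap emitted by common callers; compared with `>=`).
#' @param window_size used only to verify enough markers remain to fill at
#'   least one scan window (default 100).
#' @return object of class `reference_haplotype`: list with `markers`
#'   (data.frame `chrom`, `pos`, `qual`, `variant_id`) and `allele`
#'   (integer vector, 0 = reference allele, 1 = alternate allele, i.e. the
#'   animal's homozygous dosage / 2). Heterozygous markers inside the region
#'   are dropped with a warning.
#' @export
build_reference_haplotype <- function(vs, ref_sample, region = NULL,
                                      qual_min = 999, window_size = 100L) {
  if (!ref_sample %in% vs$samples)
    stop("reference sample not in variant set: ", ref_sample)
  v <- vs$variants
  keep <- rep(TRUE, nrow(v))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- v$chrom == rg$chrom & v$pos >= rg$start & v$pos <= rg$end
  }
  keep <- keep & !is.na(v$qual) & v$qual >= qual_min
  g <- vs$geno[, ref_sample]
  het <- keep & !is.na(g) & g == 1L
  if (any(het))
    warning(sum(het), " heterozygous marker(s) of ", ref_sample,
            " dropped from the reference region")
  keep <- keep & !is.na(g) & g != 1L
  if (sum(keep) < window_size)
    stop("only ", sum(keep), " usable reference markers; at least ",
         window_size, " needed for one window")
  v <- v[keep, , drop = FALSE]
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  structure(list(markers = data.frame(chrom = v$chrom, pos = v$pos,
                                      qual = v$qual,
                                      variant_id = v$variant_id,
                                      stringsAsFactors = FALSE),
                 allele = as.integer(g[keep][ord] / 2L),
                 qual_min = qual_min),
            class = "reference_haplotype")
}

#' @export
print.reference_haplotype <- function(x, ...) {
  cat("reference_haplotype: ", nrow(x$markers), " markers, ",
      x$markers$chrom[1], ":", min(x$markers$pos), "-", max(x$markers$pos),
      " (QUAL >= ", x$qual_min, ")\n", sep = "")
  invisible(x)
}

# opposing-homozygote indicator: dosage 0 against a reference alternate
# allele, or dosage 2 against a reference reference allele; heterozygotes
# and matching homozygotes are never in opposition
opposing_matrix <- function(geno, ref_allele) {
  opp <- sweep(geno, 2L, 2L * (1L - ref_allele), `==`)
  opp[is.na(geno)] <- NA
  opp
}

#' Opposing-homozygote inconsistency rate in one marker window
#'
#' The fraction of non-missing markers in the window at which an individual
#' is homozygous for the allele opposite the reference haplotype's allele.
#' Heterozygous and matching-homozygous markers contribute zero: the test
#' works on unphased genotypes and never falsely flags a heterozygous
#' carrier of the reference haplotype.
#'
#' @param geno integer vector of dosages at the reference markers (in
#'   marker order), or a matrix (individuals x markers).
#' @param ref a [build_reference_haplotype()] result, or a bare 0/1 allele
#'   vector.
#' @param window integer indices of the markers forming the window.
#' @return inconsistency rate(s) in `[0, 1]`; `NA` when every marker in the
#'   window is missing for the individual.
#' @export
window_inconsistency_rate <- function(geno, ref, window) {
  allele <- if (inherits(ref, "reference_haplotype")) ref$allele else ref
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  if (ncol(geno) != length(allele))
    stop("genotypes must be aligned with the reference markers")
  if (any(window < 1L) || any(window > length(allele)))
    stop("window indices out of marker range")
  opp <- opposing_matrix(geno[, window, drop = FALSE], allele[window])
  n_obs <- rowSums(!is.na(opp))
  rate <- rowSums(opp, na.rm = TRUE) / n_obs
  rate[n_obs == 0L] <- NA_real_
  if (nrow(opp) == 1L) rate[[1L]] else rate
}

#' Sliding-window scan of opposing-homozygote inconsistency
#'
#' Slides windows of `window_size` reference markers across the region
#' (stride `step`), computes each individual's inconsistency rate per
#' window, and counts the individuals whose rate reaches the threshold.
#' Each window's count is attributed to the position of its central marker
#' (the 51st of 100).
#'
#' @param geno matrix of dosages, individuals in rows, reference markers in
#'   columns (aligned with `ref$markers`).
#' @param ref a [build_reference_haplotype()] result.
#' @param window_size markers per window (default 100).
#' @param threshold inconsistency rate at or above which an individual is
#'   flagged (default 0.05, i.e. at least 5 opposing homozygotes in a
#'   complete 100-marker window).
#' @param step window stride in markers (default 1).
#' @return object of class `window_profile`: data.frame with columns
#'   `window_start` (first marker index), `anchor_index`, `anchor_pos`,
#'   `n_flagged`; attributes `window_size`, `threshold`, `n_individuals`,
#'   `chrom`, and `rates` (individuals x windows matrix). Windows in which
#'   an individual has no observed marker are skipped for that individual.
#' @export
scan_profiles <- function(geno, ref, window_size = 100L, threshold = 0.05,
                          step = 1L) {
  allele <- ref$allele
  m <- length(allele)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                         dimnames = list("ind1", NULL))
  if (ncol(geno) != m)
    stop("genotypes must be aligned with the reference markers")
  if (m < window_size)
    stop("fewer markers (", m, ") than one window (", window_size, ")")
  starts <- seq.int(1L, m - window_size + 1L, by = step)
  anchor_off <- as.integer(floor(window_size / 2) + 1L) # 51st of 100
  anchors <- starts + anchor_off - 1L

  n_ind <- nrow(geno)
  opp <- opposing_matrix(geno, allele)
  obs <- !is.na(opp)
  opp[!obs] <- FALSE
  # windowed sums via cumulative sums along markers
  csum <- function(x) {
    cs <- cbind(0, t(apply(x, 1L, cumsum)))
    cs[, starts + window_size, drop = FALSE] - cs[, starts, drop = FALSE]
  }
  w_opp <- csum(opp)
  w_obs <- csum(obs)
  rates <- w_opp / w_obs
  rates[w_obs == 0L] <- NA_real_
  flagged <- !is.na(rates) & rates >= threshold
  out <- data.frame(window_start = starts, anchor_index = anchors,
                    anchor_pos = ref$markers$pos[anchors],
                    n_flagged = colSums(flagged))
  rownames(rates) <- rownames(geno)
  structure(out, class = c("window_profile", "data.frame"),
            window_size = as.integer(window_size), threshold = threshold,
            n_individuals = n_ind, chrom = ref$markers$chrom[1],
            rates = rates)
}

#' Scan a control cohort with the same settings
#'
#' Convenience wrapper running [scan_profiles()] on a cohort of non-carrier
#' animals from the same breeds: in the absence of a shared ancestral
#' segment the window counts around the focal site are expected to stay
#' positive. An empty cohort yields an all-zero profile with a warning.
#'
#' @inheritParams scan_profiles
#' @return a `window_profile` (see [scan_profiles()]).
#' @export
control_scan <- function(geno, ref, window_size = 100L, threshold = 0.05,
                         step = 1L) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  if (nrow(geno) == 0L) {
    warning("empty control cohort: all window counts are 0")
    geno <- matrix(NA_integer_, nrow = 1L, ncol = length(ref$allele))
  }
  scan_profiles(geno, ref, window_size = window_size,
                threshold = threshold, step = step)
}

#' @export
plot.window_profile <- function(x, focal_pos = NULL, ...) {
  graphics::plot(x$anchor_pos, x$n_flagged, type = "l",
                 xlab = paste0("position on ", attr(x, "chrom"),
                               " (window anchor)"),
                 ylab = "individuals with >= 5% opposing homozygotes", ...)
  if (!is.null(focal_pos))
    graphics::abline(v = focal_pos, lty = 2)
  invisible(x)
}

#' Delimit the IBD block around a focal mutation
#'
#' The block is the maximal contiguous run of windows in which no
#' individual reaches the inconsistency threshold, whose anchor span
#' contains the focal position. Bounds are the anchor positions of the
#' run's first and last windows. If the focal position does not sit inside
#' any zero-count run, the scan found no shared segment and an empty block
#' is returned with a diagnostic.
#'
#' @param profile a `window_profile` from [scan_profiles()].
#' @param focal_pos 1-based position of the focal mutation; must lie within
#'   the scanned anchor range.
#' @return object of class `ibd_block`: list with `chrom`, `start`, `end`
#'   (anchor positions), `length_bp` (`end - start`), `n_windows`,
#'   `contains_focal`, `empty`, and `reason` when empty.
#' @export
detect_ibd_block <- function(profile, focal_pos) {
  if (focal_pos < min(profile$anchor_pos) ||
      focal_pos > max(profile$anchor_pos))
    stop("focal position ", focal_pos, " outside the scanned anchor range")
  zero <- profile$n_flagged == 0L
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  chrom <- attr(profile, "chrom")
  for (j in which(r$values)) {
    lo <- profile$anchor_pos[starts[j]]
    hi <- profile$anchor_pos[ends[j]]
    if (lo <= focal_pos && focal_pos <= hi) {
      return(structure(list(chrom = chrom, start = lo, end = hi,
                            length_bp = hi - lo,
                            n_windows = ends[j] - starts[j] + 1L,
                            contains_focal = TRUE, empty = FALSE),
                       class = "ibd_block"))
    }
  }
  structure(list(chrom = chrom, start = NA_real_, end = NA_real_,
                 length_bp = NA_real_, n_windows = 0L,
                 contains_focal = FALSE, empty = TRUE,
                 reason = paste0("window at focal position ", focal_pos,
                                 " has a positive inconsistency count: ",
                                 "no shared segment detected")),
            class = "ibd_block")
}

#' @export
print.ibd_block <- function(x, ...) {
  if (x$empty) {
    cat("ibd_block: empty (", x$reason, ")\n", sep = "")
  } else {
    cat("ibd_block: ", x$chrom, ":", x$start, "-", x$end, " (",
        format(x$length_bp / 1000, digits = 4), " kb, ", x$n_windows,
        " zero-count windows)\n", sep = "")
  }
  invisible(x)
}
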