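#' Extract fixed-size marker-window haplotypes per animal
#'
#' Concatenates the phased alleles of each animal over a fixed window of
#' markers (50 SNPs in the published test) into haplotype strings. Animals
#' with any missing allele inside the window are flagged and should be
#' excluded downstream.
#'
#' @param hm a [haplotype_matrix()].
#' @param marker_window integer indices of the window's markers, in order.
#' @param window_size required window size (default 50); a mismatch with
#'   `length(marker_window)` is an error.
#' @return data.frame with columns `sample`, `hap1`, `hap2` (allele-code
#'   strings) and `complete` (no missing allele in either haplotype).
#' @export
extract_window_haplotypes <- function(hm, marker_window,
                                      window_size = 50L) {
  marker_window <- as.integer(marker_window)
  if (length(marker_window) != window_size)
    stop("marker window has ", length(marker_window),
         " markers; expected ", window_size)
  if (any(marker_window < 1L) || any(marker_window > nrow(hm$markers)))
    stop("marker window indices out of range")
  hap_string <- function(h) {
    m <- h[marker_window, , drop = FALSE]
    apply(m, 2L, function(a) paste(ifelse(is.na(a), ".", a), collapse = ""))
  }
  s1 <- hap_string(hm$h1)
  s2 <- hap_string(hm$h2)
  data.frame(sample = hm$samples, hap1 = s1, hap2 = s2,
             complete = !grepl(".", s1, fixed = TRUE) &
               !grepl(".", s2, fixed = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify window haplotypes by focal-mutation status
#'
#' Anchors each distinct haplotype to the focal allele it travels with,
#' using animals of known focal genotype: a haplotype seen in at least one
#' homozygous-mutant (Fs/Fs) animal and never in a homozygous wild-type
#' (Wt/Wt) animal is `Fs`; seen in Wt/Wt and never Fs/Fs it is `Wt`; seen
#' in both it is `undetermined`. Haplotypes seen only in heterozygotes
#' cannot be anchored and default to `undetermined` (an optional iterative
#' deduction uses the Wt-anchored partner haplotype of a heterozygote to
#' deduce its other haplotype as Fs, and vice versa).
#'
#' @param haps data.frame from [extract_window_haplotypes()]; animals with
#'   `complete == FALSE` are ignored.
#' @param meta data.frame with columns `sample_id` and `focal_genotype`
#'   (values `"Fs/Fs"`, `"Fs/Wt"`, `"Wt/Wt"`, `"unknown"`).
#' @param deduce_het if `TRUE`, iterate the heterozygote deduction until a
#'   fixed point (off by default: the conservative reading).
#' @return object of class `haplotype_status_table`: data.frame with one
#'   row per distinct haplotype (`haplotype`, `n_fsfs`, `n_fswt`, `n_wtwt`,
#'   `status`) plus attribute `fractions` (shares of Fs / Wt /
#'   undetermined among classified haplotypes).
#' @export
classify_haplotypes <- function(haps, meta, deduce_het = FALSE) {
  meta$sample_id <- as.character(meta$sample_id)
  gt <- meta$focal_genotype[match(haps$sample, meta$sample_id)]
  use <- haps$complete & !is.na(gt) & gt %in% c("Fs/Fs", "Fs/Wt", "Wt/Wt")
  if (!any(use & gt %in% c("Fs/Fs", "Wt/Wt")))
    stop("no homozygous reference animals: nothing can be classified")
  long <- data.frame(
    haplotype = c(haps$hap1[use], haps$hap2[use]),
    genotype = rep(gt[use], 2L),
    sample = rep(haps$sample[use], 2L),
    stringsAsFactors = FALSE)
  tab <- as.data.frame.matrix(table(long$haplotype,
                                    factor(long$genotype,
                                           c("Fs/Fs", "Fs/Wt", "Wt/Wt"))))
  out <- data.frame(haplotype = rownames(tab),
                    n_fsfs = tab[["Fs/Fs"]], n_fswt = tab[["Fs/Wt"]],
                    n_wtwt = tab[["Wt/Wt"]],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$status <- ifelse(out$n_fsfs > 0 & out$n_wtwt == 0, "Fs",
                ifelse(out$n_wtwt > 0 & out$n_fsfs == 0, "Wt",
                       "undetermined"))
  if (isTRUE(deduce_het)) {
    # a heterozygote pairs one Fs and one Wt haplotype: an anchored partner
    # determines the other side, unless contradicted by a homozygote
    het <- long$genotype == "Fs/Wt"
    pair <- split(long$haplotype[het], long$sample[het])
    repeat {
      changed <- FALSE
      st <- stats::setNames(out$status, out$haplotype)
      for (p in pair) {
        if (length(p) != 2L) next
        s <- st[p]
        for (k in 1:2) {
          other <- s[3L - k]
          if (s[k] == "undetermined" && other %in% c("Fs", "Wt")) {
            target <- if (other == "Wt") "Fs" else "Wt"
            i <- match(p[k], out$haplotype)
            # only safe when no homozygote evidence contradicts
            if ((target == "Fs" && out$n_wtwt[i] == 0) ||
                (target == "Wt" && out$n_fsfs[i] == 0)) {
              out$status[i] <- target
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
  }
  fr <- table(factor(out$status, c("Fs", "Wt", "undetermined")))
  structure(out, class = c("haplotype_status_table", "data.frame"),
            fractions = fr / sum(fr))
}

#' @export
print.haplotype_status_table <- function(x, ...) {
  fr <- attr(x, "fractions")
  cat("haplotype_status_table: ", nrow(x), " distinct haplotypes\n",
      sep = "")
  cat(sprintf("  Fs %.2f%%   Wt %.2f%%   undetermined %.2f%%\n",
              100 * fr[["Fs"]], 100 * fr[["Wt"]],
              100 * fr[["undetermined"]]))
  invisible(x)
}

#' Look up the status of haplotype strings
#'
#' @param haplotype character vector of haplotype strings.
#' @param table a [classify_haplotypes()] result.
#' @return character vector with values `"Fs"`, `"Wt"`, `"undetermined"`,
#'   or `"not_documented"` for haplotypes absent from the table.
#' @export
haplotype_status <- function(haplotype, table) {
  st <- table$status[match(haplotype, table$haplotype)]
  st[is.na(st)] <- "not_documented"
  st
}

#' Infer focal genotypes from haplotype-status pairs
#'
#' Maps each animal's two haplotype statuses to a focal genotype:
#' (Fs, Fs) -> Fs/Fs, (Fs, Wt) -> Fs/Wt, (Wt, Wt) -> Wt/Wt; any
#' undetermined or undocumented member yields `"unknown"`.
#'
#' @param haps data.frame from [extract_window_haplotypes()].
#' @param table a [classify_haplotypes()] result.
#' @return data.frame with columns `sample`, `status1`, `status2`,
#'   `genotype`.
#' @export
infer_variant_genotype <- function(haps, table) {
  s1 <- haplotype_status(haps$hap1, table)
  s2 <- haplotype_status(haps$hap2, table)
  s1[!haps$complete] <- "undetermined"
  s2[!haps$complete] <- "undetermined"
  n_fs <- (s1 == "Fs") + (s2 == "Fs")
  anchored <- s1 %in% c("Fs", "Wt") & s2 %in% c("Fs", "Wt")
  genotype <- rep("unknown", nrow(haps))
  genotype[anchored] <- c("Wt/Wt", "Fs/Wt", "Fs/Fs")[n_fs[anchored] + 1L]
  data.frame(sample = haps$sample, status1 = s1, status2 = s2,
             genotype = genotype, stringsAsFactors = FALSE)
}

#' Allele-frequency trajectory over birth-year sliding windows
#'
#' Computes the focal (Fs) allele frequency among informative haplotypes —
#' those anchored as Fs or Wt — for sliding birth-year windows. An animal
#' born in year y contributes its two haplotype statuses to every window
#' whose `[start, start + window_years)` span contains y; each point is
#' labelled by the window midpoint.
#'
#' @param statuses data.frame from [infer_variant_genotype()] (columns
#'   `sample`, `status1`, `status2`).
#' @param meta data.frame with columns `sample_id`, `birth_year`.
#' @param window_years window span in years (default 7, about one
#'   generation in the studied breeding systems).
#' @param step_years stride between window starts (default 1).
#' @return object of class `freq_trajectory`: data.frame with columns
#'   `center_year`, `n_informative`, `freq` (`NA` when a window holds no
#'   informative haplotype).
#' @export
frequency_trajectory <- function(statuses, meta, window_years = 7L,
                                 step_years = 1L) {
  meta$sample_id <- as.character(meta$sample_id)
  year <- meta$birth_year[match(statuses$sample, meta$sample_id)]
  if (anyNA(year))
    stop("every animal needs a birth year; missing for ",
         sum(is.na(year)), " animal(s)")
  st <- c(statuses$status1, statuses$status2)
  yy <- rep(year, 2L)
  informative <- st %in% c("Fs", "Wt")
  last_start <- max(year) - window_years + 1L
  starts <- if (last_start < min(year)) min(year) else
    seq.int(min(year), last_start, by = step_years)
  rows <- lapply(starts, function(s) {
    inw <- yy >= s & yy < s + window_years
    n_fs <- sum(inw & informative & st == "Fs")
    n_wt <- sum(inw & informative & st == "Wt")
    data.frame(center_year = s + (window_years - 1) / 2,
               n_informative = n_fs + n_wt,
               freq = if (n_fs + n_wt > 0) n_fs / (n_fs + n_wt) else NA_real_)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("freq_trajectory", "data.frame"),
            window_years = as.integer(window_years))
}

#' @export
plot.freq_trajectory <- function(x, ...) {
  graphics::plot(x$center_year, 100 * x$freq, type = "b", pch = 16,
                 xlab = "birth year (window midpoint)",
                 ylab = "Fs allele frequency (%)", ...)
  invisible(x)
}
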