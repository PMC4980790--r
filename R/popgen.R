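#' Allele frequency from genotype counts
#'
#' @param n_wtwt,n_fswt,n_fsfs counts of homozygous wild-type,
#'   heterozygous, and homozygous mutant animals (vectorised).
#' @return mutant (Fs) allele frequency
#'   `(2 n_FsFs + n_FsWt) / (2 (n_WtWt + n_FsWt + n_FsFs))`.
#' @export
allele_frequency_from_counts <- function(n_wtwt, n_fswt, n_fsfs) {
  total <- n_wtwt + n_fswt + n_fsfs
  if (any(total <= 0)) stop("genotype counts sum to zero")
  (2 * n_fsfs + n_fswt) / (2 * total)
}

#' Pearson chi-square test of independence on a genotype-count table
#'
#' Wraps the standard Pearson test (no continuity correction) for cohort x
#' genotype contingency tables, e.g. sequenced founder bulls versus animals
#' reported for loss of vision. An optional collapse merges heterozygous
#' and homozygous wild-type animals into a single "carrier of a wild-type
#' allele" column, testing homozygous mutants against the rest.
#'
#' @param tab matrix (cohorts x genotype classes), counts >= 0, at least
#'   two rows and two columns.
#' @param collapse `"none"` (default) tests the full table;
#'   `"homalt_vs_rest"` collapses to 2 columns (`n_FsFs`, rest) and assumes
#'   column order (Wt/Wt, Fs/Wt, Fs/Fs).
#' @return list with `statistic`, `df`, `p_value`, `expected`, `table`.
#' @export
chi_square_independence <- function(tab, collapse = c("none",
                                                      "homalt_vs_rest")) {
  collapse <- match.arg(collapse)
  tab <- as.matrix(tab)
  if (collapse == "homalt_vs_rest") {
    if (ncol(tab) != 3L) stop("homalt_vs_rest collapse expects 3 columns")
    tab <- cbind(rest = tab[, 1L] + tab[, 2L], homalt = tab[, 3L])
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero expected cell(s): merge categories before testing")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected, table = tab)
}

#' Hardy-Weinberg incidence of affected homozygotes
#'
#' Under random mating, a recessive allele at frequency q produces affected
#' homozygotes at frequency q^2 — one in every `1/q^2` animals.
#'
#' @param q allele frequency, `0 < q <= 1`.
#' @return list with `fraction` (`q^2`) and `one_in_n` (`1/q^2` rounded to
#'   the nearest integer).
#' @export
hwe_homozygote_incidence <- function(q) {
  if (any(q <= 0) || any(q > 1)) stop("allele frequency must be in (0, 1]")
  list(fraction = q^2, one_in_n = round(1 / q^2))
}

#' Per-cohort genotype fractions from a count table
#'
#' @param tab matrix (cohorts x genotype classes).
#' @return list with `fractions` (row-normalised matrix) and `percent`
#'   (the same in percent rounded to one decimal, the usual presentation).
#' @export
genotype_frequency_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) <= 0)) stop("every cohort needs a positive total")
  fr <- sweep(tab, 1L, rowSums(tab), `/`)
  list(fractions = fr, percent = round(100 * fr, 1))
}
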