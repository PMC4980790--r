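#' Convert a physical segment length to genetic map length
#'
#' Uses a constant local map rate; by default 1 cM per Mb, i.e. 1 Morgan
#' per 100 Mb.
#'
#' @param length_bp segment length in base pairs (> 0).
#' @param cm_per_mb map rate in centiMorgan per megabase (default 1).
#' @return genetic length in Morgans.
#' @export
bp_to_morgans <- function(length_bp, cm_per_mb = 1) {
  if (any(length_bp <= 0)) stop("segment length must be positive")
  length_bp * cm_per_mb * 1e-8
}

#' Generations to the common ancestor from a shared segment
#'
#' Two animals sharing an identical-by-descent segment of genetic length c
#' Morgans inherited it from a common ancestor who lived about 1/(2c)
#' generations ago: each meiosis erodes the shared haplotype by
#' recombination at rate c per generation on either lineage.
#'
#' @param c genetic segment length in Morgans (> 0).
#' @return number of generations, full precision.
#' @export
generations_from_segment <- function(c) {
  if (any(c <= 0)) stop("segment length in Morgans must be positive")
  1 / (2 * c)
}

#' Calendar-year range from a generation count
#'
#' @param g number of generations (> 0).
#' @param interval generation interval bounds in years, `c(low, high)`;
#'   default `c(5, 7)`, spanning natural-mating and modern breeding
#'   schemes.
#' @return named numeric `c(low, high)` in years.
#' @export
years_from_generations <- function(g, interval = c(5, 7)) {
  if (any(g <= 0)) stop("generations must be positive")
  if (interval[1] > interval[2]) stop("interval must be c(low, high)")
  c(low = g * interval[1], high = g * interval[2])
}

#' Date a founder mutation from its shared IBD segment
#'
#' Chains [bp_to_morgans()], [generations_from_segment()] and
#' [years_from_generations()], recording every intermediate. The formula is
#' derived for a pair of animals; applied to the segment shared by all
#' carriers it over-estimates the age, since the n-carrier intersection is
#' shorter than a typical pairwise segment (see the package vignette, where
#' this bias is quantified on simulated panels).
#'
#' @param block an `ibd_block` from [detect_ibd_block()], or a segment
#'   length in base pairs.
#' @param cm_per_mb map rate (default 1 cM/Mb).
#' @param generation_years generation-interval bounds in years
#'   (default `c(5, 7)`).
#' @return object of class `age_estimate`: list with `segment_bp`,
#'   `cm_per_mb`, `c_morgans`, `generations` (full precision) and `years`
#'   (low/high).
#' @export
date_mutation <- function(block, cm_per_mb = 1, generation_years = c(5, 7)) {
  if (inherits(block, "ibd_block")) {
    if (isTRUE(block$empty) || is.na(block$length_bp) || block$length_bp <= 0)
      stop("cannot date a mutation from an empty IBD block")
    segment_bp <- block$length_bp
  } else {
    segment_bp <- as.numeric(block)
  }
  c_morgans <- bp_to_morgans(segment_bp, cm_per_mb)
  g <- generations_from_segment(c_morgans)
  structure(list(segment_bp = segment_bp, cm_per_mb = cm_per_mb,
                 c_morgans = c_morgans, generations = g,
                 generation_years = generation_years,
                 years = years_from_generations(g, generation_years)),
            class = "age_estimate")
}

#' Round a generation estimate for presentation
#'
#' @param x an `age_estimate` (or bare number of generations).
#' @param nearest rounding grain in generations (1 for nearest integer,
#'   5 for the coarser "approximately" convention).
#' @return rounded generations.
#' @export
round_generations <- function(x, nearest = 1) {
  g <- if (inherits(x, "age_estimate")) x$generations else x
  nearest * round(g / nearest)
}

#' @export
print.age_estimate <- function(x, nearest = 5, ...) {
  cat("age_estimate from a ", format(x$segment_bp / 1000, digits = 4),
      "-kb shared segment (", x$cm_per_mb, " cM/Mb):\n", sep = "")
  cat("  c = ", format(x$c_morgans, digits = 4), " Morgans\n", sep = "")
  cat("  1/(2c) = ", format(x$generations, digits = 5),
      " generations (~", round_generations(x, nearest), ")\n", sep = "")
  cat("  ", format(x$years[["low"]], digits = 4), " to ",
      format(x$years[["high"]], digits = 4), " years at ",
      x$generation_years[1], "-", x$generation_years[2],
      "-year generations\n", sep = "")
  invisible(x)
}
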