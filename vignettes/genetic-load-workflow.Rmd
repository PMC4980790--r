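---
title: "Screening genetic load and dating a founder mutation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genetic load and dating a founder mutation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genload)
```

This vignette is the package's account of the science behind its five
analysis stages and of the design choices made where the methods left room
for interpretation. The running example throughout is the kind of dataset
the package targets: a multi-breed panel of sequenced artificial-insemination
bulls carrying an old recessive frameshift mutation (mutant allele "Fs",
wild type "Wt") whose late-onset phenotype escaped routine surveillance.

## 1. The deleterious-variant screen

### Model

A variant is retained as putatively deleterious and non-rare when all of the
following hold, evaluated in this fixed order (the order affects only which
rule a removal is attributed to, never the final set):

1. **biallelic** — multi-allelic records are dropped at parse time;
2. **candidate consequence** — a loss-of-function term (initiator codon,
   splice acceptor or donor, frameshift, stop lost or gained) or a missense
   with SIFT score at most `sift_max_for_missense`;
3. **site quality** — QUAL strictly above `qual_min`, MQ within
   `mq_allowed`, missing-genotype fraction strictly below `missing_max`;
4. **singleton exclusion** — total alternate-allele count across the panel
   at least 2: an allele observed in a single heterozygote is more likely a
   calling artifact than a segregating polymorphism;
5. **frequency** — alternate-allele frequency at least `maf_min` in at
   least one breed with at least `breed_min_n` genotyped animals;
6. **repeat exclusion** — the variant's position (for indels, the whole REF
   span) must not overlap the repeat track;
7. **same-codon exclusion** — pairs of SNVs in one codon of one gene are
   both removed, because independent annotation of adjacent substitutions
   mispredicts the joint amino-acid change;
8. **gene symbol** — an official symbol must be present (a bare Ensembl
   gene identifier does not count).

### Parameters

| parameter | default | unit | why |
|---|---|---|---|
| `qual_min` | 30 | phred | strict `>`: QUAL = 30 sites are borderline calls |
| `mq_allowed` | {59, 60} | phred | uniquely-mapping reads on standard aligners |
| `missing_max` | 0.05 | fraction | strict `<`: genotyping completeness floor |
| `maf_min` | 0.05 | fraction | "non-rare": drift alone rarely carries artifacts this high |
| `breed_min_n` | 20 | animals | frequency estimates below this are too noisy |
| `sift_max_for_missense` | 0 | score | only the most confident damaging missense calls; relaxing to 0.05 would flood the gene list |

Two points were genuinely open and are settled as package defaults, each
switchable:

* **≥ vs >** for the frequency threshold: the package uses `>=` 5 %
  (`maf_strict = FALSE` by default), the reading consistent with
  "segregating at 5 % or more"; `maf_strict = TRUE` selects the strict
  reading.
* **Breed eligibility basis**: the 20-animal minimum is counted on animals
  *genotyped at the site*, not panel membership, so the eligibility basis
  always matches the frequency denominator. Missingness is assessed over
  the whole panel by default (`missing_per_breed = FALSE`).
* **Which allele's frequency**: the screen tests the alternate
  (putatively deleterious) allele's frequency rather than the folded minor
  allele frequency — the deleterious allele is the quantity of interest and
  for these variants the two coincide in practice.

Note an unavoidable interaction: a true singleton (one copy in a panel of
tens of animals) necessarily also fails the 5 % rule; the cascade attributes
it to the singleton rule, which comes first.

## 2. The across-breed IBD scan

### Model

All carriers of a unique ancestral mutation share, around the focal site,
a haplotype inherited from the founder, progressively shortened by
recombination. The scan detects it without phasing carriers: only an
animal homozygous for the allele *opposite* the reference haplotype's
allele ("opposing homozygote") is evidence against carrying that haplotype;
heterozygotes are always compatible. The reference haplotype itself is read
off the genome of one homozygous mutant inside its smallest homozygous
region, keeping markers at the caller's maximum quality (QUAL ≥ 999).

For each animal and each sliding window of `window_size = 100` reference
SNPs, the inconsistency rate is the fraction of non-missing markers in
opposition. Windows are slid one SNP at a time (`step = 1`; a stride was
not inherent to the method, and stride 1 gives the finest anchor grid) and
each window's count of animals with rate ≥ `threshold = 0.05` is attributed
to its central (51st) marker position. The 5 % allowance absorbs sequencing
errors in low-coverage animals and de novo mutations accumulated on the old
haplotype; with complete 100-marker windows it equals ≥ 5 opposing
homozygotes. The IBD block is the maximal run of zero-count windows whose
anchor span contains the focal position; its bounds are anchor positions
(central markers), the only coordinate the method itself defines. If the
focal window has a positive count, the scan reports an empty block — the
carriers share no segment at the method's resolution.

Missing genotypes leave both numerator and denominator (the method is a
rate over observed markers); a window entirely missing for an animal is
skipped for that animal.

### Numerical conventions and degenerate inputs

* Rates are invariant under a consistent swap of allele labels.
* The reference scanned against itself is everywhere consistent.
* An empty control cohort yields an all-zero profile with a warning rather
  than an error, so control plots degrade gracefully.
* Fewer retained reference markers than one window is an error: no window
  statistic is computable.

## 3. Dating the founder mutation

Two animals sharing an IBD segment of genetic length $c$ Morgans trace it
to a common ancestor about $g = 1/(2c)$ generations back: the expected
two-sided retained length after $g$ meioses on each of two lineages is
$1/g$ Morgans, each side being exponential with rate $2g$. Physical length
converts at `cm_per_mb = 1` (1 cM ≈ 1 Mb, the genome-wide average for
cattle), and generations map to years through a 5–7-year generation
interval spanning natural-service and modern AI breeding.

Two caveats are deliberate:

* **Presentation rounding only.** The core returns full precision;
  `round_generations(x, nearest = 5)` reproduces the "approximately"
  convention of published estimates. An 88.6-kb segment gives
  $c = 8.86\times10^{-4}$ M, $g = 564.33 \approx 565$, 2822–3950 years.
* **The pairwise formula on an n-carrier intersection.** Applied to the
  segment shared by *all* carriers, $1/(2c)$ over-estimates age, because
  the intersection of $n$ eroded segments is stochastically shorter than a
  pairwise one (each side is the minimum of $n$ exponentials). The package
  implements the estimator as defined — and the simulator makes the bias
  measurable rather than hidden: `simulate_segment_lengths()` draws from
  the generative model, for which $E[1/(2c)] = g$ exactly when $c$ is one
  two-sided pairwise segment (a Gamma(2, 2g) variable), and the acceptance
  suite verifies this consistency by Monte Carlo at $g = 100$ over
  $10^5$ segments.

## 4. The haplotype-status test and frequency trajectories

### Model

With the focal variant genotyped on a SNP chip for a reference cohort but
not for historical animals, a 50-SNP haplotype window around the mutation
serves as a proxy genotype. Each distinct haplotype is anchored by the
homozygous reference animals that carry it: seen in a homozygous mutant and
never in a homozygous wild type it tags Fs; the converse tags Wt; seen in
both it is **undetermined**; haplotypes only ever seen in heterozygotes
cannot be anchored and are also undetermined by default. At application
time, a haplotype absent from the table is **not documented**. An animal's
genotype follows from its pair of statuses, with any unanchored member
giving "unknown".

The conservative default for heterozygote-only haplotypes was a real
choice: a heterozygote whose other haplotype is Wt-anchored *must* carry Fs
on the first, and `deduce_het = TRUE` iterates that deduction to a fixed
point (never overriding homozygote evidence). It is off by default because
the anchoring definition is stated purely in terms of homozygotes, and the
deduction propagates any phasing error in a heterozygote into the table.

Allele frequencies over time are computed on haplotypes, not animals: for
each sliding birth-year window of `window_years = 7` (about one generation)
stepped by 1 year, the frequency is #Fs / (#Fs + #Wt) over the informative
haplotypes of animals born in `[start, start + 7)`, labelled at the window
midpoint. Undetermined and undocumented haplotypes leave numerator *and*
denominator, which is unbiased as long as sharing a haplotype between
backgrounds is not correlated with the allele itself — the simulator draws
shared haplotypes with equal probability from both backgrounds for exactly
this reason. A window with no informative haplotype reports an absent
frequency rather than zero.

## 5. Genotype-count statistics

* Allele frequency from genotype counts:
  $(2\,n_{FsFs} + n_{FsWt}) / (2\,(n_{WtWt}+n_{FsWt}+n_{FsFs}))$,
  displayed at two decimals in percent.
* Case/control association uses the Pearson chi-square on the 2×3 genotype
  table without continuity correction (`stats::chisq.test(correct =
  FALSE)` under the hood); a `collapse = "homalt_vs_rest"` option tests
  homozygous mutants against all carriers of a wild-type allele. The two
  conventions answer slightly different questions and give different
  p-values; the package exposes both rather than blending them. Zero
  expected cells are an error suggesting category merging.
* Expected incidence of affected homozygotes under Hardy–Weinberg is
  $q^2$, reported also as "one in $1/q^2$" rounded to the nearest integer
  (q = 0.27 gives one in 14).

The tests validate the chi-square p-value against an independent
margin-preserving Monte Carlo null (random tables with the observed margins
via `r2dtable`, $10^5$ draws). That comparison is made on tables with all
expected counts well above 10 and moderate p-values, where the asymptotic
distribution is an accurate description of the conditional null; at extreme
tail p-values on small tables the two nulls legitimately differ by more
than Monte Carlo error, which is a property of the approximation, not a
defect of either computation.

## 6. What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, with ground truth
recorded alongside:

* `simulate_screen_vcf()` writes an annotated VCF, breed map and repeat
  BED in which each variant violates one planned rule (or none): the
  canonical fixture is 12 variants over 3 breeds × 25 animals.
  `simulate_random_variants()` draws attributes straddling every threshold
  for property tests against a brute-force oracle.
* `simulate_carrier_panel()` plants one ancestral haplotype, erodes each
  carrier's copy by two one-sided exponentials at rate $2g$ per Morgan
  (homozygous carriers get two independently eroded copies, and are
  shielded from opposition over their union), and fills everything else
  with background alleles drawn independently per marker from
  Uniform(0.1, 0.9) frequencies. Its descriptive defaults mirror the
  published regime: 38 carriers (35 heterozygous, 3 homozygous), a 38-animal
  control group, ~9 448 markers at ~124-bp spacing (~1.17 Mb), true age
  565 generations.
* `simulate_trajectory_cohort()` draws ~33 animals per year over 1975–2015
  with a linear Fs-frequency path from 0.40 to 0.27, Fs and Wt alleles
  tagged by disjoint 50-SNP haplotype pools (5 and 20 haplotypes) plus a
  4 % shared ("undetermined") draw.

Deliberate simplifications, and their consequences for interpreting green
tests:

* **No background linkage disequilibrium** — markers are independent given
  their frequencies. This is enough to exercise the opposing-homozygote
  logic, but real panels have LD-induced runs of compatibility, so
  real-data blocks are fuzzier than simulated ones; passing recovery tests
  bounds algorithmic error, not biological uncertainty.
* **Star genealogy** — carriers descend independently from the founder.
  Under that model the published regime itself (38 carriers, g = 565) has
  an expected all-carrier intersection of only a few kilobases, *below* the
  100-SNP window resolution: real carrier sets share much more because
  their lineages coalesce recently within breeds. The block-recovery
  property is therefore tested on a detectable configuration chosen once —
  10 carriers, true age 25 generations, 4 000 markers at 250-bp spacing —
  and seeds whose planted intersection is narrower than one window are
  excluded as below the method's resolution (an empty block is then the
  *correct* answer). Recovery is asserted to within one window span, the
  anchor discretisation of the method.
* **No phasing or genotyping error** in trajectory cohorts, so anchored
  genotype inference is exact by construction; the corresponding test
  checks the logic, not robustness to chip error.

## 7. Problem sizes and tolerances used by the test suite

Chosen as a balance between statistical resolution and a suite that runs in
seconds; they are the package's own test design:

* screen-vs-oracle equivalence: 200-variant random fixtures, 3–5 replicates;
* IBD recovery: 20 seeds of the detectable configuration above, tolerance
  one window span (100 markers × 250 bp);
* dating consistency: $10^5$ segments at $g = 100$, tolerance 5 % (the
  estimator has a heavy right tail — $1/c$ has barely-infinite variance —
  so the sample mean converges slowly and a tight tolerance would test the
  tail, not the identity);
* trajectory endpoints: 4 binomial standard errors at the realised window
  sizes;
* chi-square Monte Carlo: $10^5$ draws, tolerance 4 Monte Carlo standard
  deviations plus 0.005 for the asymptotic approximation.

## 8. Known limitations

* The screen reproduces a filtering *procedure*; published headline counts
  from specific consortium datasets depend on those genotypes and cannot be
  re-derived from synthetic panels.
* Dating ignores uncertainty: no likelihood, no confidence interval, and
  the n-carrier intersection bias discussed above. A recombination-clock
  likelihood estimator is out of scope.
* The haplotype-status test assumes the 50-SNP window is short enough that
  recombination between window and focal site is negligible on the
  time-scale of the cohort; violations would surface as undetermined
  haplotypes, not as wrong anchors, which is the safe failure mode.
* `in_intervals()` and the repeat rule treat intervals as closed on the
  0-based half-open BED convention; a variant is excluded if any REF base
  overlaps, which for long indels is deliberately conservative.
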