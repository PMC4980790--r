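Package: genload
Title: Genetic-Load Variant Screening and Founder-Mutation Dating in Cattle
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse-genetics toolkit for characterising the genetic load of
    livestock populations from multi-breed whole-genome variant panels.
    Implements a filter cascade selecting non-rare putative loss-of-function
    variants from annotated VCF data; an across-breed identity-by-descent scan
    around a focal mutation using a sliding-window opposing-homozygote
    inconsistency rule; recombination-clock dating of a founder mutation from
    the shared segment length (g = 1/(2c)); a multi-marker haplotype-status
    test that reconstructs allele-frequency trajectories across birth-year
    cohorts; genotype-count statistics (allele frequencies, case/control
    chi-square, Hardy-Weinberg homozygote incidence); and a synthetic-data
    generator with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    vcfR,
    IRanges,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
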