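Package: Ypopgen
Title: Sex-Biased Demography and Background Selection on the Human Y Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether low diversity on a non-recombining
    chromosome is explained by sex-biased demography or by purifying
    (background) selection. Implements the algebra linking male and female
    effective numbers to per-chromosome-class effective sizes, a neutral
    Kingman coalescent under piecewise-constant demography, a forward
    Wright-Fisher simulator of a non-recombining haploid chromosome carrying
    sites under a gamma distribution of fitness effects, an approximate
    likelihood (Poisson mixture over simulated segregating-site counts) for
    the number of sites under purifying selection, observed-data diversity
    statistics (pi, segregating sites, folded site frequency spectrum,
    interval-mask filtering, divergence normalization), and a synthetic-data
    generator producing study-shaped VCF/BED bundles with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
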