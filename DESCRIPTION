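Package: recombPool
Title: Recombination Rate Estimation from Pooled Allele Frequencies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates genetic maps and windowed recombination rates (cM/Mb)
    for biparental segregating populations from pooled genotyping or pooled
    sequencing allele frequencies, without individual genotype calls. Allele
    frequency differences of physically neighbouring polymorphic loci, scaled
    by the decadic logarithm of their physical distance, are accumulated into
    a raw pool genetic map (PGM) whose length is then calibrated by a
    non-linear model of genotyping depth and population size (nPGM). Includes
    a seedable Haldane (no-interference) meiosis simulator for F2 and
    recombinant inbred line populations, a binomial pooled-sequencing read
    model, a two-point EM Haldane map baseline from individual genotypes,
    sliding-window recombination rate summaries, per-parent general
    recombination effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
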