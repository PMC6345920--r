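Package: poescan
Title: Mapping Imprinted QTL from Parental Parent-of-Origin Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step association mapping of imprinted quantitative trait
    loci (iQTL) in populations where phenotyped progeny are un-genotyped
    and genotyped parents are un-phenotyped. Parent-of-origin effects
    (POEs) are first estimated for each parent as the difference between
    its two sex-of-parent-specific transmitting abilities, using a reduced
    imprinting mixed model fitted by REML with a pedigree covariance
    structure. The estimated POEs are then parent-average corrected,
    deregressed and weighted (adapting Garrick-style deregression) and
    regressed on un-ordered marker gene counts; at a biallelic imprinted
    locus this regression estimates the imprinting effect. Includes the
    closed-form single-locus theory, a quantitative-genetic population
    simulator with marker-QTL linkage disequilibrium and recombination,
    pedigree, gametic and genomic relationship matrices, per-marker mixed
    models with conditional Wald F-tests, genotype quality control and
    genome-/chromosome-wide FDR control, and a replication harness for
    simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
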