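Package: wheatTEbias
Title: Transposable-Element Insertions and Homoeolog Expression Bias in
    Allopolyploid Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links transposable-element (TE) insertions within gene bodies to
    genome-specific (homoeolog-biased) expression in allohexaploid bread
    wheat. Provides TE-in-gene overlap calling from GFF3/TSV annotations,
    classification of homoeologous groups (dyads, triads, tetrads) as
    monomorphic or polymorphic for TE presence against a conditional-binomial
    null model, nearest-centroid assignment of triads to seven relative
    expression-contribution categories, contingency-table screens of TE
    superfamilies and subfamilies against expression categories with
    Benjamini-Hochberg control, GO term enrichment by one-sided Fisher's
    exact test, and a synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
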