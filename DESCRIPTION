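Package: litscape
Title: Literature-Landscape Networks and Enrichment for Gene-Annotated
    Publication Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bibliometric analysis of gene-annotated publication corpora:
    country and city extraction from raw author affiliations via a gazetteer,
    country- and city-level collaboration co-occurrence matrices with
    chord-diagram export, gene-gene literature co-occurrence networks with
    strict count thresholding and community detection, an exact
    hypergeometric enrichment test of highly-studied genes against city gene
    sets with a threshold sweep and Bonferroni correction, time-interval
    regressions of the yearly share of genetics research, and Ward
    hierarchical clustering of gene-by-city publication profiles. Includes a
    synthetic corpus generator with planted ground truth so every stage of
    the pipeline can be validated end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    jsonlite,
    yaml,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
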