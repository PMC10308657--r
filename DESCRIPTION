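Package: gwasviz
Title: Visualisation, Annotation and Comparison of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for viewing, annotating and comparing genome-wide
    association study (GWAS) summary statistics. Provides Manhattan,
    regional, locuszoom-style and effect-size comparison plots for one or
    many datasets, built on a declarative, renderer-independent plot
    specification; helper functions for lead-variant extraction within
    genomic windows, nearest-gene annotation against a gene/exon track,
    region resolution from gene names, variant identifiers or coordinate
    strings, and cross-dataset variant matching with allele harmonisation
    and effect flipping; plus deterministic simulators for summary
    statistics with planted association peaks and matching synthetic gene
    tracks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    patchwork,
    rlang,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
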