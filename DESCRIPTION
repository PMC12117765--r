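Package: mycoenrich
Title: Functional Category Enrichment Analysis for Fungal and Non-Model Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Overrepresentation analysis of KOG/COG, Gene Ontology, and KEGG
    functional categories in user-supplied protein lists, aimed at fungal and
    other non-model genomes. Builds background frequency models from
    JGI-MycoCosm-style annotation exports, KEGG orthology link files, or
    eggNOG-mapper output; tests categories with a one-sided hypergeometric
    test (or a chi-squared alternative) with Benjamini-Hochberg false
    discovery rate control; propagates GO annotations up the ontology graph
    and reduces redundant GO results by shared ancestry; converts identifiers
    via GTF/GFF3 gene models; and renders bar or lollipop enrichment plots.
    A seeded synthetic-annotation generator with planted enrichment supports
    fully offline testing of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
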