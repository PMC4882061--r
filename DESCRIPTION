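Package: glomcyto
Title: Tissue-Restricted Protein-Protein Interaction Network Analysis of
    the Glomerular Cytoskeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles a glomerulus-restricted cytoskeleton gene universe
    from annotation and tissue-enrichment gene sets (with mouse-to-human
    ortholog mapping), integrates confidence-scored protein-protein
    interactions with a noisy-OR combined score and a stringency
    threshold, induces the tissue-restricted interaction network and
    computes its topology (degree, betweenness centrality, component
    structure), classifies genes by direction-consistent differential
    expression across five proteinuric glomerular diseases to nominate
    candidate genes, reconstructs bridge-node subnetworks around the
    candidates, and prioritizes candidate-disease associations by
    correlating phenotype similarity with network closeness to known
    disease genes.  A seeded synthetic-data generator with planted ground
    truth makes the whole pipeline testable without any external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
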