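Package: emapMotifs
Title: Triplet Motif Analysis of Quantitative Epistasis (E-MAP) Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing quantitative genetic-interaction (E-MAP)
    score matrices as signed networks of epistatic interactions. S-score
    matrices are thresholded at symmetric percentile cutoffs into positive
    and negative interaction networks, closed three-gene motifs are
    enumerated and classified (NNN, NNP, NPP, PPP), and motif enrichment is
    assessed against a signed-degree-preserving edge-switching null model.
    Position-coded Fisher exact tests, edge-context fold changes, within
    triplet epistatic profile correlations, and positional gene-set
    enrichment relate motif classes and positions to functional annotation
    channels (protein complexes, pathways, phenotypes, Gene Ontology terms,
    physical and genetic interactions, homology). A synthetic E-MAP
    generator with planted complexes, redundant pathway pairs, and pathway
    regulators supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Epistasis, NetworkEnrichment,
    SystemsBiology
RoxygenNote: 7.3.3
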