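Package: netsig
Title: Disease Gene Signatures from Interactome and Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-medicine pipeline for enlarging a known disease-gene
    set into a validated disease module. Candidate genes are ranked on a
    protein-protein interaction network by hypergeometric connectivity
    significance (DIAMOnD-style iterative expansion), bounded by a
    sliding-window functional-enrichment criterion, and intersected with
    switch genes detected in a case/control gene co-expression network
    (SWIM-style heat cartography: k-means clusters, average neighbour
    correlation, within-module degree and clusterphobic coefficient).
    The assembled module is validated against degree-preserving random
    gene sets drawn from the interactome. Includes synthetic generators
    with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
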