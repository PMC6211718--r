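Package: subnetDE
Title: Detection of Differentially Expressed Gene Subnetworks from
    Prior-Primed Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies highly connected, differentially expressed gene
    subnetworks by priming phenotype-specific weighted co-expression
    networks with a priori gene-gene relations (for example
    protein-protein interactions), detecting modules from the
    topological overlap measure with a dynamic dendrogram cut, screening
    the modules for differential expression with preranked gene set
    enrichment analysis, and assessing whole-pipeline significance by
    permutation of either input source (prior-network labels or
    expression gene labels).  Includes signature-score and survival
    analyses of the selected subnetworks, a synthetic-data generator
    with planted modules for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    limma,
    survival,
    withr
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
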