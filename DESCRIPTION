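Package: cecmarker
Title: Marker Discovery for Human Corneal Endothelial Cells from Bulk
    Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a marker-discovery workflow for human corneal
    endothelial cells (CECs) from gene-level RNA-seq count tables: reads-per-
    million normalization, hierarchical clustering of samples, threshold-based
    filter cascades that select genes highly expressed in young CEC, old CEC
    and cultured CEC but depleted or absent in corneal stroma, a four-rule
    marker-adequacy flaw taxonomy, functional-category screens, category
    percentage and hypergeometric over-representation statistics for gene
    lists, and housekeeping-normalized qPCR relative quantification (ddCt)
    with Welch group statistics. A seeded negative-binomial simulator plants
    marker archetypes so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, Sequencing, qPCR, Classification
RoxygenNote: 7.3.3
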