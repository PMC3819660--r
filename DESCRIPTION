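Package: orgflow
Title: Organ-Specific Transcriptome Comparison with Multi-Sample TMM
    Normalization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for comparing de novo assembled transcriptomes across
    organs without replicates. Estimates length- and depth-scaled scaffold
    abundances from read-count tables, computes n-sample trimmed-mean
    (TMM-style) normalization factors against a synthetic reference profile
    built from commonly expressed genes, partitions scaffolds into
    chloroplast, mitochondrial and nuclear classes from tabular BLAST hits,
    provides common-set correlation statistics and correlation-based
    agglomerative clustering, and annotates metabolic-pathway topologies
    with fold-change classes (direction, magnitude tier, highest sample) to
    support substance-flow reading. Includes a seeded synthetic-data
    generator with analytic ground truth for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Transcriptomics, Normalization, GeneExpression, Pathways
RoxygenNote: 7.3.3
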