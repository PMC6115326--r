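Package: TissuePref
Title: Tissue-Preferential Gene Selection and In-Silico Characterization
        for Expression Compendia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Identifies genes preferentially expressed in a target tissue
        (e.g. rice root hairs) from a multi-tissue log2-intensity expression
        compendium via expression filtering, K-means clustering, cross-tissue
        elimination and a fold-change rule, and characterizes the resulting
        gene set in silico: repeat-based Gene Ontology fold-enrichment with
        hypergeometric tests, promoter cis-element scanning (IUPAC consensus
        or position weight matrix, both strands), coexpression-refined
        protein-protein interaction networks, and cross-species conservation
        statistics over ortholog pair tables. Ships a synthetic-data
        generator with planted ground truth so every stage is testable
        without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, BiocGenerics, S4Vectors,
        GenomicRanges, GenomeInfoDb, Biostrings, SummarizedExperiment,
        limma, rtracklayer, igraph, yaml
Suggests: testthat (>= 3.0.0), withr
biocViews: Transcriptomics, GeneExpression, Clustering, Network,
        MotifAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
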