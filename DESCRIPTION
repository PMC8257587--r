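Package: sennet
Title: Permutation Statistics, NMF Clustering, and Process Networks for
    Senescence Omics
Version: 0.1.0
Authors@R:
    person("Sennet", "Maintainers", email = "maintainers@sennet.dev",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting senescence-associated
    changes in nucleocytoplasmic proteomes and transcriptomes.  Implements
    permutation empirical-null differential expression for TMT reporter-ion
    peptide tables (channel permutation) and microarray log2-intensity
    matrices (sample-label permutation with Stouffer-combined p-values),
    peptide-to-protein rollup, non-negative matrix factorization clustering
    of multi-model fold-change matrices with permutation activation
    significance, model-similarity statistics (sibling-peptide fold-change
    correlation, hypergeometric set overlap, average-linkage model
    dendrograms), hypergeometric gene-set enrichment, and Sorensen-Dice
    process-network construction.  Includes seeded generators for synthetic
    TMT, microarray, fold-change and gene-set inputs with planted truth.
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
    optparse,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
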