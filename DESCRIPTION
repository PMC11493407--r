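Package: airomics
Title: Proteogenomic Analysis Toolkit for Air-Pollution-Associated Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the analysis stages used to characterize
    air-pollution-associated lung adenocarcinoma cohorts from somatic
    mutations and multi-omic profiles: 96-channel trinucleotide mutation
    spectra and flank-context distributions; non-negative matrix
    factorization of spectra into mutational signatures with cosine-similarity
    matching against reference catalogs and non-negative least-squares
    exposure refitting; binomial enrichment tests for missense mutations at
    structure-resolved protein-protein interaction interfaces (oncoPPIs) with
    false-discovery-rate control; single-sample gene-set enrichment (ssGSEA)
    and kinase-substrate enrichment (KSEA) scoring; multi-omic consensus
    clustering with CDF/delta-area selection of the cluster number, cluster
    marker isolation and cluster-clinical association tests; and evaluation of
    a linear radiomic signature with ROC/AUC and confusion-matrix utilities.
    A synthetic-data module generates inputs with the statistical structure
    each stage assumes, so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
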