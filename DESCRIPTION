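Package: subnetmark
Title: Subnetwork Biomarker Discovery from Integrated Expression and
    Copy-Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for deriving subnetwork markers from a two-class
    gene expression matrix and a list of copy-number-altered genes.
    Differentially expressed genes are intersected with the copy-number
    list to obtain seed genes, a protein-protein interaction network is
    expanded around the seeds and clustered with a from-scratch Markov
    Cluster Algorithm, and the surviving subnetworks are scored per
    sample as the mean z-score of up-regulated members minus that of
    down-regulated members. Subnetwork scores feed a linear support
    vector machine for tumor/normal classification and a Cox
    proportional-hazards risk score with median-split Kaplan-Meier and
    log-rank survival analysis. Seeded synthetic generators emulate
    every input with known ground truth, and a gene-set
    over-representation module reports fold enrichment against
    user-supplied annotation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    igraph,
    jsonlite,
    pROC,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
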