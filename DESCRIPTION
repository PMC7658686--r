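Package: cogmwas
Title: Downstream Statistics for COG-Level Metagenome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical toolkit for the downstream stages of a functional
    metagenome-wide association study. Starting from a sample-by-function
    (COG) abundance table and clinical metadata, the package normalizes and
    aggregates functional profiles, clusters samples with PCA and
    partitioning around medoids, identifies differentially abundant
    functions with permutational one-way ANOVA and rank-sum contrasts under
    Benjamini-Hochberg FDR control, builds per-group signed co-occurrence
    networks with category-level complexity indices, selects functional
    biomarkers by combined differential-abundance and clinical-correlation
    filters, and evaluates one-vs-rest random-forest discrimination with
    cross-validated ROC/AUC. A compositional count simulator with planted
    enrichments, correlated blocks, and clinical links makes every stage
    testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    randomForest,
    igraph
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
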