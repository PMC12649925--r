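Package: mlhgrn
Title: Multi-Layer Hierarchical Gene Regulatory Networks from Drought
    Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers multi-layer hierarchical gene regulatory networks
    (ML-hGRN) above a metabolic pathway gene layer using bottom-up
    weighted random forests (BWERF): recursive random-forest importance
    ranking with iterative elimination of weak transcription factors,
    Gaussian-mixture separation of regulatory layers, and
    correlation-based gene-metabolite linking.  Also provides the
    surrounding screening workflow for time-course drought experiments:
    FPKM computation and a simplified negative-binomial Wald test with
    Benjamini-Hochberg FDR for differential expression, KNN imputation,
    QC coefficient-of-variation filtering, OPLS-DA/VIP scoring for
    differential metabolite accumulation, and K-means clustering of
    temporal metabolite profiles.  Seeded simulators with planted ground
    truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    mclust
Config/testthat/edition: 3
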