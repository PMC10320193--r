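Package: subbias
Title: Subgenome-Resolved Expression Bias Analysis for Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of genes whose acquired-haploid (1n) subgenome expression
    departs from the primary-diploid (2n) expression relationship in
    allopolyploid yeast RNA-seq data. Provides subgenome-restricted and
    shared-core library normalization, collapsed (2n + 1n) counts,
    per-sample 2n-vs-1n regression with prediction-interval outlier calls and
    per-population consistency consolidation, haploid-fraction statistics,
    one-vs-rest negative-binomial Wald differential expression with
    transcriptomic-signature calling, hypergeometric gene-ontology enrichment,
    ordination summaries (PCA, Spearman), an ortholog-transfer hit filter for
    BLAST tabular output, and a negative-binomial count simulator with known
    truth emulating the population structure of allotriploid
    Brettanomyces bruxellensis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
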