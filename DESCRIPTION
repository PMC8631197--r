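Package: spongenet
Title: Competing Endogenous RNA Network Construction from Multi-Class
    RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lncRNA- and circRNA-based competing endogenous RNA
    (ceRNA) networks from two-condition whole-transcriptome count data.
    Provides per-class normalization (FPKM, TPM, SRPBM), a
    negative-binomial Wald test with Benjamini-Hochberg adjustment,
    canonical miRNA seed-site (MRE) scanning with an optional
    miRanda-style duplex score, Pearson co-expression and anti-correlation
    filters, a hypergeometric sponge test, hypergeometric
    over-representation analysis and a running-sum GSEA with permutation
    null, plus immunohistochemistry H-score and qPCR 2^-ddCT
    quantification. A synthetic-data generator with planted sponge
    triplets gives every stage a ground truth, and a single orchestrator
    runs the whole pipeline reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
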